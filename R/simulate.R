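#' Specify a synthetic cohort
#'
#' Collects everything the generator needs to emulate a caregiver cohort:
#' ordinal responses arise by discretising a common-factor model
#' \eqn{z_{ij} = \lambda_j \theta_i + \sqrt{1-\lambda_j^2}\,\epsilon_{ij}}
#' (standard-normal trait and noise) at per-item thresholds; missingness is
#' completely at random; external covariates are drawn conditionally on the
#' trait to hit target correlations in expectation; binary groupings shift
#' the trait by a standardised amount.
#'
#' Defaults reproduce the reference study conditions: 135 respondents,
#' the packaged CLCF-SF instrument, 1.6\% missingness, covariate-trait
#' correlations of 0.48 (depression), 0.41/0.43 (state/trait anxiety) and
#' -0.37 (lung function), and latent group shifts of 0.37 (unwell vs well)
#' and 0.26 (recent hospital admission vs none).
#'
#' @param n_respondents Cohort size.
#' @param instrument An `instrument` whose items are simulated.
#' @param loadings Per-item common-factor loadings in `[0, 1)`; recycled.
#' @param thresholds Optional list of per-item strictly increasing latent
#'   cut-points (length `n_categories - 1`); default places categories at
#'   equal marginal probabilities.
#' @param missing_rate Probability a cell is missing, in `[0, 1)`.
#' @param covariate_correlations Named target correlations with the latent
#'   trait, each in `(-1, 1)`.
#' @param group_effects Named standardised latent mean shifts for binary
#'   groupings (balanced Bernoulli membership).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_respondents = 135,
                        instrument = clcf_sf(),
                        loadings = 0.5,
                        thresholds = NULL,
                        missing_rate = 0.016,
                        covariate_correlations = c(
                          depression = 0.48,
                          anxiety_state = 0.41,
                          anxiety_trait = 0.43,
                          lung_function = -0.37
                        ),
                        group_effects = c(unwell = 0.37, admitted = 0.26),
                        seed = 1L) {
  k <- nrow(instrument)
  loadings <- rep_len(loadings, k)
  if (any(loadings < 0 | loadings >= 1)) {
    abort("Loadings must lie in [0, 1).")
  }
  if (missing_rate < 0 || missing_rate >= 1) abort("missing_rate must be in [0, 1).")
  if (length(covariate_correlations) > 0 &&
      any(abs(covariate_correlations) >= 1)) {
    abort(paste0("Covariate-trait correlations must have absolute value < 1 ",
                 "(the implied joint correlation matrix is otherwise not positive definite)."))
  }
  if (is.null(thresholds)) {
    thresholds <- lapply(instrument$n_categories, function(nc) {
      qnorm(seq_len(nc - 1L) / nc)
    })
  }
  if (length(thresholds) != k) abort("Need one threshold vector per item.")
  for (j in seq_len(k)) {
    tj <- thresholds[[j]]
    if (length(tj) != instrument$n_categories[j] - 1L) {
      abort(paste0("Item '", instrument$id[j], "' needs ",
                   instrument$n_categories[j] - 1L, " thresholds."))
    }
    if (any(diff(tj) <= 0)) {
      abort(paste0("Thresholds for item '", instrument$id[j],
                   "' must be strictly increasing."))
    }
  }
  structure(
    list(
      n_respondents = as.integer(n_respondents),
      instrument = instrument,
      loadings = loadings,
      thresholds = thresholds,
      missing_rate = missing_rate,
      covariate_correlations = covariate_correlations,
      group_effects = group_effects,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# Discretise latent responses for a given trait vector.
likert_from_trait <- function(spec, theta) {
  inst <- spec$instrument
  n <- length(theta)
  k <- nrow(inst)
  out <- matrix(NA_integer_, n, k, dimnames = list(NULL, inst$id))
  for (j in seq_len(k)) {
    z <- spec$loadings[j] * theta + sqrt(1 - spec$loadings[j]^2) * rnorm(n)
    out[, j] <- inst$min_code[j] + findInterval(z, spec$thresholds[[j]])
  }
  if (spec$missing_rate > 0) {
    out[matrix(runif(n * k) < spec$missing_rate, n, k)] <- NA_integer_
  }
  out
}

#' Simulate ordinal Likert responses
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with `respondent_id` and one integer column per item
#'   (`NA` = missing). The drawn latent traits are attached as attribute
#'   `"truth"`.
#' @examples
#' simulate_likert(cohort_spec(n_respondents = 5, seed = 1))
#' @export
simulate_likert <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    theta <- rnorm(spec$n_respondents)
    m <- likert_from_trait(spec, theta)
    out <- as_tibble(as.data.frame(m))
    out <- dplyr::bind_cols(
      tibble(respondent_id = seq_len(spec$n_respondents)), out
    )
    attr(out, "truth") <- list(theta = theta)
    out
  })
}

#' Simulate a full cohort: responses, covariates and group labels
#'
#' Group membership is drawn first (balanced Bernoulli per grouping); the
#' latent trait is standard normal plus the stated shift for each group a
#' respondent belongs to. Each covariate `v` with target correlation
#' `rho` is `rho * theta_std + sqrt(1 - rho^2) * noise`, so
#' `cor(v, theta) = rho` in expectation.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `cohort_sim` with tibbles `responses`,
#'   `covariates`, `groups` and a `truth` list carrying the latent traits.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_respondents
    gnames <- names(spec$group_effects)
    groups <- matrix(0L, n, length(spec$group_effects),
                     dimnames = list(NULL, gnames))
    for (g in seq_along(spec$group_effects)) {
      groups[, g] <- rbinom(n, 1L, 0.5)
    }
    shift <- as.numeric(groups %*% spec$group_effects)
    theta <- rnorm(n) + shift
    # theoretical scale of theta, for exact target correlations
    s_theta <- sqrt(1 + sum(spec$group_effects^2 * 0.25))
    theta_std <- (theta - sum(spec$group_effects) * 0.5) / s_theta
    cnames <- names(spec$covariate_correlations)
    covs <- matrix(NA_real_, n, length(cnames), dimnames = list(NULL, cnames))
    for (v in seq_along(cnames)) {
      rho <- spec$covariate_correlations[[v]]
      covs[, v] <- rho * theta_std + sqrt(1 - rho^2) * rnorm(n)
    }
    m <- likert_from_trait(spec, theta)
    responses <- dplyr::bind_cols(
      tibble(respondent_id = seq_len(n)),
      as_tibble(as.data.frame(m))
    )
    structure(
      list(
        responses = responses,
        covariates = dplyr::bind_cols(tibble(respondent_id = seq_len(n)),
                                      as_tibble(as.data.frame(covs))),
        groups = dplyr::bind_cols(tibble(respondent_id = seq_len(n)),
                                  as_tibble(as.data.frame(groups))),
        truth = list(theta = theta, theta_std = theta_std)
      ),
      class = "cohort_sim"
    )
  })
}

#' Simulate responses from a Rating Scale Model
#'
#' Draws ordinal responses (codes `1..m`) from the RSM: for person
#' \eqn{\theta}, item difficulty \eqn{\beta_i} and shared thresholds
#' \eqn{\tau_1..\tau_{m-1}},
#' \eqn{P(X = c) \propto \exp\{c(\theta-\beta_i) - \sum_{l\le c}\tau_l\}}
#' with categories counted from 0 internally.
#'
#' @param difficulties Named or unnamed per-item difficulties (logits).
#' @param thresholds Shared category thresholds, length `m - 1`.
#' @param persons Latent person values.
#' @param missing Optional logical mask (persons x items); `TRUE` cells are
#'   structurally missing (not administered) and returned as `NA`.
#' @param seed Optional integer seed.
#' @return A tibble with `respondent_id` and one column per item.
#' @export
simulate_rsm <- function(difficulties, thresholds, persons, missing = NULL,
                         seed = NULL) {
  k <- length(difficulties)
  m <- length(thresholds) + 1L
  ids <- names(difficulties)
  if (is.null(ids)) ids <- paste0("t", seq_len(k))
  if (!is.null(missing)) {
    stopifnot(is.logical(missing),
              nrow(missing) == length(persons), ncol(missing) == k)
  }
  with_seed(seed, {
    out <- matrix(NA_integer_, length(persons), k, dimnames = list(NULL, ids))
    for (j in seq_len(k)) {
      p <- rsm_probs(persons, difficulties[j], thresholds)  # n x m
      u <- runif(length(persons))
      cum <- t(apply(p, 1L, cumsum))
      out[, j] <- 1L + as.integer(rowSums(u > cum + 1e-15))
      out[out[, j] > m, j] <- m
    }
    if (!is.null(missing)) out[missing] <- NA_integer_
    dplyr::bind_cols(tibble(respondent_id = seq_along(persons)),
                     as_tibble(as.data.frame(out)))
  })
}
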