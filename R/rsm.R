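# RSM category probabilities for person vector theta at one item.
# Categories are 0..m-1; P(X=c) prop exp(c*(theta-beta) - sum_{l<=c} tau_l).
rsm_probs <- function(theta, beta, tau) {
  m <- length(tau) + 1L
  cats <- 0:(m - 1L)
  psi <- c(0, cumsum(tau))
  eta <- outer(theta - beta, cats) - rep(psi, each = length(theta))
  eta <- eta - apply(eta, 1L, max)
  e <- exp(eta)
  e / rowSums(e)
}

# Expand free parameters into (beta, tau) under the identification
# constraint sum(tau) = 0 (latent trait is N(0,1); without the constraint
# a constant can be traded between difficulties and thresholds).
rsm_expand <- function(par, k, m) {
  beta <- par[seq_len(k)]
  if (m == 2L) {
    tau <- 0
  } else {
    free <- par[k + seq_len(m - 2L)]
    tau <- c(free, -sum(free))
  }
  list(beta = beta, tau = tau)
}

# log P table: k x m x Q for quadrature nodes.
rsm_logp_table <- function(beta, tau, nodes) {
  k <- length(beta)
  m <- length(tau) + 1L
  arr <- array(NA_real_, c(k, m, length(nodes)))
  for (i in seq_len(k)) {
    arr[i, , ] <- t(log(rsm_probs(nodes, beta[i], tau)))
  }
  arr
}

# Per-person log-likelihood at each node: n x Q. x is n x k 0-based codes
# with NA for structurally missing cells.
rsm_person_loglik <- function(x, logp) {
  n <- nrow(x)
  Q <- dim(logp)[3L]
  ll <- matrix(0, n, Q)
  for (i in seq_len(ncol(x))) {
    obs <- which(!is.na(x[, i]))
    if (length(obs) == 0L) next
    ll[obs, ] <- ll[obs, ] + matrix(logp[i, , ], dim(logp)[2L], Q)[x[obs, i] + 1L, , drop = FALSE]
  }
  ll
}

#' Fit a Rating Scale Model by marginal maximum likelihood
#'
#' Polytomous Rasch-family model with one difficulty per item and category
#' thresholds shared across items, estimated by an EM algorithm over a
#' standard-normal latent trait with fixed-node quadrature (41 nodes on
#' \[-6, 6\]). Missing cells (e.g. treatments a child does not receive —
#' missing by design) contribute nothing to the likelihood. Identification:
#' latent mean fixed at 0, free item difficulties, thresholds summing to
#' zero. Standard errors come from the observed information of the item
#' parameters; person scores are posterior means (EAP).
#'
#' @param data Data frame of ordinal responses on a shared category scale
#'   (codes `min_code..min_code + n_categories - 1`; optional
#'   `respondent_id`). `NA` = not administered.
#' @param items Item columns; default all non-identifier columns.
#' @param n_categories Number of response categories; default inferred
#'   from the observed code range.
#' @param min_code Lowest category code in the data (default the observed
#'   minimum).
#' @param tol Convergence tolerance on the marginal log-likelihood change.
#' @param max_iter Maximum EM iterations.
#' @param n_nodes,node_range Quadrature grid.
#' @return An object of class `rsm_fit` with `difficulties` (tibble of
#'   item, difficulty, se), `thresholds`, `persons` (tibble of EAP scores
#'   and posterior SDs), `loglik`, `loglik_trace`, `iterations`,
#'   `converged`, `excluded` (inestimable items). `tidy()` returns the
#'   item table; `glance()` the fit summary.
#' @export
fit_rsm <- function(data, items = NULL, n_categories = NULL, min_code = NULL,
                    tol = 1e-5, max_iter = 500L, n_nodes = 41L,
                    node_range = c(-6, 6)) {
  m0 <- response_matrix(data, items)
  if (all(is.na(m0))) abort("No observed responses.")
  min_code <- min_code %||% min(m0, na.rm = TRUE)
  x <- m0 - min_code
  n_categories <- n_categories %||% (max(x, na.rm = TRUE) + 1L)
  m <- as.integer(n_categories)
  if (m < 2L) abort("Need at least 2 response categories.")
  if (any(x < 0 | x > m - 1L, na.rm = TRUE)) {
    abort("Responses outside the stated category range.")
  }
  # inestimable items: no observations, or all observed responses identical
  item_ok <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[!is.na(x[, j]), j]
    length(v) > 0L && length(unique(v)) > 1L
  }, logical(1))
  excluded <- colnames(x)[!item_ok]
  if (length(excluded) > 0L) {
    warn(paste0("Excluding inestimable item(s) (all responses in one ",
                "category or never administered): ",
                paste(excluded, collapse = ", ")))
    x <- x[, item_ok, drop = FALSE]
  }
  if (ncol(x) < 1L) abort("No estimable items remain.")
  keep_person <- rowSums(!is.na(x)) > 0L
  x_fit <- x[keep_person, , drop = FALSE]
  k <- ncol(x_fit)
  ids <- colnames(x_fit)

  nodes <- seq(node_range[1L], node_range[2L], length.out = n_nodes)
  wq <- dnorm(nodes)
  wq <- wq / sum(wq)

  n_free <- k + max(0L, m - 2L)
  par <- numeric(n_free)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L

  marginal_ll <- function(par) {
    pp <- rsm_expand(par, k, m)
    logp <- rsm_logp_table(pp$beta, pp$tau, nodes)
    ll <- rsm_person_loglik(x_fit, logp)
    mx <- apply(ll, 1L, max)
    sum(mx + log((exp(ll - mx) %*% wq)[, 1L]))
  }

  repeat {
    iter <- iter + 1L
    pp <- rsm_expand(par, k, m)
    logp <- rsm_logp_table(pp$beta, pp$tau, nodes)
    ll <- rsm_person_loglik(x_fit, logp)
    mx <- apply(ll, 1L, max)
    num <- exp(ll - mx) * rep(wq, each = nrow(ll))
    marg <- rowSums(num)
    ll_new <- sum(mx + log(marg))
    ll_trace <- c(ll_trace, ll_new)
    post <- num / marg  # n x Q posterior weights
    if (abs(ll_new - ll_old) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll_new
    # E-step expected category-by-node counts per item
    r <- vector("list", k)
    for (i in seq_len(k)) {
      obs <- which(!is.na(x_fit[, i]))
      ind <- matrix(0, length(obs), m)
      ind[cbind(seq_along(obs), x_fit[obs, i] + 1L)] <- 1
      r[[i]] <- crossprod(ind, post[obs, , drop = FALSE])  # m x Q
    }
    # M-step: maximise expected complete-data log-likelihood
    q_obj <- function(p) {
      pp <- rsm_expand(p, k, m)
      lp <- rsm_logp_table(pp$beta, pp$tau, nodes)
      -sum(vapply(seq_len(k), function(i) sum(r[[i]] * lp[i, , ]), numeric(1)))
    }
    par <- nlminb(par, q_obj)$par
  }

  pp <- rsm_expand(par, k, m)
  # observed information of the item parameters
  H <- tryCatch(optimHess(par, function(p) -marginal_ll(p)),
                error = function(e) NULL)
  se <- rep(NA_real_, k)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      d <- diag(V)[seq_len(k)]
      se[d > 0] <- sqrt(d[d > 0])
    }
  }
  if (anyNA(se)) warn("Some standard errors could not be computed.")

  # EAP person scores on the final posterior
  logp <- rsm_logp_table(pp$beta, pp$tau, nodes)
  ll <- rsm_person_loglik(x_fit, logp)
  mx <- apply(ll, 1L, max)
  num <- exp(ll - mx) * rep(wq, each = nrow(ll))
  post <- num / rowSums(num)
  eap <- as.numeric(post %*% nodes)
  psd <- sqrt(pmax(as.numeric(post %*% nodes^2) - eap^2, 0))
  persons <- tibble(
    respondent_id = respondent_ids(data)[keep_person],
    eap = eap, posterior_sd = psd,
    n_answered = rowSums(!is.na(x_fit))
  )

  if (!converged) warn(paste0("EM did not converge in ", iter, " iterations."))
  structure(
    list(
      difficulties = tibble(item = ids, difficulty = pp$beta, se = se),
      thresholds = pp$tau,
      persons = persons,
      loglik = ll_trace[length(ll_trace)],
      loglik_trace = ll_trace,
      iterations = iter,
      converged = converged,
      excluded = excluded,
      n_categories = m,
      min_code = min_code
    ),
    class = "rsm_fit"
  )
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat(sprintf(
    "Rating Scale Model: %d items, %d persons, %d categories\n",
    nrow(x$difficulties), nrow(x$persons), x$n_categories))
  cat(sprintf("  logLik %.2f after %d EM iterations (%s)\n", x$loglik,
              x$iterations, if (x$converged) "converged" else "NOT converged"))
  cat("  thresholds:", paste(sprintf("%.2f", x$thresholds), collapse = ", "), "\n")
  print(x$difficulties)
  invisible(x)
}

#' @export
tidy.rsm_fit <- function(x, ...) x$difficulties

#' @export
glance.rsm_fit <- function(x, ...) {
  tibble(loglik = x$loglik, iterations = x$iterations,
         converged = x$converged, n_items = nrow(x$difficulties),
         n_persons = nrow(x$persons), n_categories = x$n_categories)
}

#' @export
augment.rsm_fit <- function(x, ...) x$persons

#' Person scores from a fitted Rating Scale Model
#'
#' @param fit An `rsm_fit`.
#' @return Tibble of EAP scores (posterior means) and posterior SDs.
#' @export
person_scores <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  fit$persons
}

#' Compare item difficulties between two fitted Rating Scale Models
#'
#' Aligns the difficulty estimates (with standard errors) of two fits —
#' e.g. caregiver-rated and child-rated management of the same treatments
#' — into one table for plotting. Items present in only one fit are
#' dropped and listed in the `"dropped"` attribute.
#'
#' @param fit_a,fit_b `rsm_fit` objects sharing item identifiers.
#' @param labels Length-2 labels for the two fits.
#' @param sort_by Which fit's difficulty orders the table (`"a"` or `"b"`).
#' @return Tibble of class `rsm_comparison`: `item`, `difficulty_<a>`,
#'   `se_<a>`, `difficulty_<b>`, `se_<b>`, `difference`
#'   (second minus first). Plot with [autoplot()].
#' @export
compare_difficulties <- function(fit_a, fit_b, labels = c("a", "b"),
                                 sort_by = c("a", "b")) {
  sort_by <- match.arg(sort_by)
  stopifnot(inherits(fit_a, "rsm_fit"), inherits(fit_b, "rsm_fit"))
  da <- fit_a$difficulties
  db <- fit_b$difficulties
  shared <- intersect(da$item, db$item)
  if (length(shared) == 0L) abort("The two fits share no items.")
  dropped <- union(setdiff(da$item, shared), setdiff(db$item, shared))
  names(da)[2:3] <- paste0(c("difficulty_", "se_"), labels[1L])
  names(db)[2:3] <- paste0(c("difficulty_", "se_"), labels[2L])
  out <- dplyr::inner_join(da, db, by = "item")
  out$difference <- out[[paste0("difficulty_", labels[2L])]] -
    out[[paste0("difficulty_", labels[1L])]]
  ord <- order(out[[paste0("difficulty_", labels[if (sort_by == "a") 1L else 2L])]])
  out <- out[ord, ]
  attr(out, "dropped") <- dropped
  attr(out, "labels") <- labels
  class(out) <- c("rsm_comparison", class(out))
  out
}

#' @export
autoplot.rsm_comparison <- function(object, ...) {
  labels <- attr(object, "labels")
  long <- tidyr::pivot_longer(
    as_tibble(object),
    cols = -c("item", "difference"),
    names_to = c(".value", "rater"),
    names_pattern = "(difficulty|se)_(.*)"
  )
  long$item <- factor(long$item, levels = object$item)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$difficulty, y = .data$item,
                                     colour = .data$rater,
                                     shape = .data$rater)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$difficulty - .data$se,
                   xmax = .data$difficulty + .data$se),
      height = 0.25) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Item difficulty (logits, +/- SE)", y = NULL,
                  colour = "Rater", shape = "Rater",
                  title = "RSM difficulty comparison") +
    ggplot2::theme_minimal()
}
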