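# Shapiro-Wilk that tolerates large vectors: the test in stats is defined
# for 3..5000 observations, so larger vectors are thinned to a
# deterministic evenly spaced subsample of 5000.
shapiro_safe <- function(x) {
  if (length(x) > 5000L) {
    x <- x[round(seq(1L, length(x), length.out = 5000L))]
  }
  shapiro.test(x)
}

#' Normality-gated correlation
#'
#' Applies the Shapiro-Wilk test to each variable; if both pass at
#' `sw_alpha` the reported coefficient is Pearson's r, otherwise
#' Spearman's rho (the convention for skewed questionnaire covariates).
#' Both coefficients are retained in the output for transparency, along
#' with which variable triggered the method choice.
#'
#' @param data Data frame holding the two variables.
#' @param x,y Column names (strings). Rows with missing values in either
#'   are dropped (pairwise-complete analysis).
#' @param sw_alpha Significance level of the normality gate (default 0.05).
#' @return A one-row tibble: `method`, `estimate`, `p_value`, `n`,
#'   `sw_p_x`, `sw_p_y`, `pearson_r`, `spearman_rho`, `rationale`.
#' @export
cor_validity <- function(data, x, y, sw_alpha = 0.05) {
  xv <- data[[x]]
  yv <- data[[y]]
  if (is.null(xv) || is.null(yv)) abort("Both columns must exist in `data`.")
  cc <- complete.cases(xv, yv)
  xv <- xv[cc]
  yv <- yv[cc]
  n <- length(xv)
  if (n < 4L) abort("Need at least 4 complete pairs.")
  if (sd(xv) == 0 || sd(yv) == 0) {
    abort("Constant variable: correlation is undefined.")
  }
  swx <- shapiro_safe(xv)
  swy <- shapiro_safe(yv)
  both_normal <- swx$p.value >= sw_alpha && swy$p.value >= sw_alpha
  pearson <- suppressWarnings(cor.test(xv, yv, method = "pearson"))
  spearman <- suppressWarnings(cor.test(xv, yv, method = "spearman"))
  chosen <- if (both_normal) pearson else spearman
  rationale <- if (both_normal) {
    "both variables pass Shapiro-Wilk"
  } else {
    paste0(
      paste(c(x, y)[c(swx$p.value < sw_alpha, swy$p.value < sw_alpha)],
            collapse = " and "),
      " fail(s) Shapiro-Wilk"
    )
  }
  tibble(
    method = if (both_normal) "pearson" else "spearman",
    estimate = unname(chosen$estimate),
    p_value = chosen$p.value,
    n = n,
    sw_p_x = swx$p.value,
    sw_p_y = swy$p.value,
    pearson_r = unname(pearson$estimate),
    spearman_rho = unname(spearman$estimate),
    rationale = rationale
  )
}

#' Known-groups comparison of scale scores
#'
#' Independent two-sample t-test of the score between two groups, with the
#' 95\% confidence interval of the mean difference and Cohen's d from the
#' pooled standard deviation (n - 2 denominator). The classical
#' pooled-variance test is the default; `var_equal = FALSE` gives Welch.
#'
#' @param data Data frame with the score and grouping columns.
#' @param score Column name of the numeric score.
#' @param group Column name of the binary grouping (logical, 0/1 or
#'   two-level factor/character). The mean difference is "second level
#'   minus first level" with levels sorted.
#' @param var_equal Pooled-variance t-test (default `TRUE`).
#' @param level Confidence level for the mean-difference interval.
#' @return A one-row tibble: `group1`, `group2`, `n1`, `n2`,
#'   `mean_difference`, `conf_low`, `conf_high`, `t_statistic`, `df`,
#'   `p_value`, `cohens_d`.
#' @examples
#' known_groups_test(data.frame(s = c(1, 2, 3, 4, 5, 6),
#'                              g = rep(c("well", "unwell"), each = 3)),
#'                   "s", "g")
#' @export
known_groups_test <- function(data, score, group, var_equal = TRUE,
                              level = 0.95) {
  s <- data[[score]]
  g <- data[[group]]
  if (is.null(s) || is.null(g)) abort("Both columns must exist in `data`.")
  cc <- complete.cases(s, g)
  s <- s[cc]
  g <- as.factor(g)[cc]
  g <- droplevels(g)
  if (nlevels(g) != 2L) abort("Grouping must have exactly two levels.")
  lev <- sort(levels(g))
  s1 <- s[g == lev[1L]]
  s2 <- s[g == lev[2L]]
  if (length(s1) < 2L || length(s2) < 2L) {
    abort("Each group needs at least 2 observations.")
  }
  tt <- t.test(s2, s1, var.equal = var_equal, conf.level = level)
  n1 <- length(s1)
  n2 <- length(s2)
  sp <- sqrt(((n1 - 1) * var(s1) + (n2 - 1) * var(s2)) / (n1 + n2 - 2))
  d <- if (sp > 0) (mean(s2) - mean(s1)) / sp else 0
  tibble(
    group1 = lev[1L], group2 = lev[2L], n1 = n1, n2 = n2,
    mean_difference = mean(s2) - mean(s1),
    conf_low = tt$conf.int[1L], conf_high = tt$conf.int[2L],
    t_statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, cohens_d = d
  )
}

#' Full convergent and discriminant validity battery
#'
#' One normality-gated correlation per covariate and one known-groups
#' t-test per binary grouping, each on its own pairwise-complete cases
#' (external measures typically differ in availability).
#'
#' @param data Data frame holding the score, covariates and groupings.
#' @param score Column name of the scale score.
#' @param covariates Character vector of covariate column names.
#' @param groups Character vector of binary grouping column names.
#' @param sw_alpha Normality-gate level for the correlations.
#' @param var_equal Passed to [known_groups_test()].
#' @param p_adjust Optional multiple-testing adjustment for the
#'   correlation p-values, e.g. `"holm"`; default `"none"` (unadjusted,
#'   the usual reporting convention for validity batteries).
#' @return Object of class `validity_report` with tibbles `correlations`
#'   and `group_comparisons`. `tidy()` binds both into one long table.
#' @export
validity_battery <- function(data, score, covariates = character(),
                             groups = character(), sw_alpha = 0.05,
                             var_equal = TRUE, p_adjust = "none") {
  if (is.null(data[[score]])) abort(paste0("Score column '", score, "' not found."))
  missing_cols <- setdiff(c(covariates, groups), names(data))
  if (length(missing_cols) > 0L) {
    abort(paste0("Column(s) not found or misaligned: ",
                 paste(missing_cols, collapse = ", ")))
  }
  cors <- list()
  for (v in covariates) {
    n_ok <- sum(complete.cases(data[[score]], data[[v]]))
    if (n_ok < 4L) {
      warn(paste0("Skipping covariate '", v, "': only ", n_ok,
                  " complete pairs."))
      next
    }
    row <- cor_validity(data, score, v, sw_alpha = sw_alpha)
    row$measure <- v
    cors[[v]] <- row
  }
  correlations <- if (length(cors) > 0L) {
    out <- dplyr::bind_rows(cors) %>% dplyr::relocate("measure")
    out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
    out
  } else {
    tibble()
  }
  cmps <- list()
  for (g in groups) {
    row <- known_groups_test(data, score, g, var_equal = var_equal)
    row$grouping <- g
    cmps[[g]] <- row
  }
  group_comparisons <- if (length(cmps) > 0L) {
    dplyr::bind_rows(cmps) %>% dplyr::relocate("grouping")
  } else {
    tibble()
  }
  structure(
    list(correlations = correlations, group_comparisons = group_comparisons,
         score = score),
    class = "validity_report"
  )
}

#' @export
print.validity_report <- function(x, ...) {
  cat("Validity report for score '", x$score, "'\n", sep = "")
  if (nrow(x$correlations) > 0L) {
    cat("Convergent validity (normality-gated correlations):\n")
    print(dplyr::select(x$correlations, "measure", "method", "estimate",
                        "n", "p_value"))
  }
  if (nrow(x$group_comparisons) > 0L) {
    cat("Discriminant (known-groups) validity:\n")
    print(dplyr::select(x$group_comparisons, "grouping", "mean_difference",
                        "conf_low", "conf_high", "p_value", "cohens_d"))
  }
  invisible(x)
}

#' @export
tidy.validity_report <- function(x, ...) {
  parts <- list()
  if (nrow(x$correlations) > 0L) {
    parts$cor <- x$correlations %>%
      mutate(analysis = "correlation") %>%
      select("analysis", "measure", "method", "estimate", "n", "p_value")
  }
  if (nrow(x$group_comparisons) > 0L) {
    parts$grp <- x$group_comparisons %>%
      mutate(analysis = "known_groups", measure = .data$grouping,
             method = "t_test", estimate = .data$mean_difference,
             n = .data$n1 + .data$n2) %>%
      select("analysis", "measure", "method", "estimate", "n", "p_value")
  }
  dplyr::bind_rows(parts)
}
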