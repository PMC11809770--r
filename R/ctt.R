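#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' \deqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_j s_j^2}{s_T^2}\right)}
#' where \eqn{s_j^2} are the item variances and \eqn{s_T^2} the variance of
#' the total score, all with the `n - 1` denominator. `standardized = TRUE`
#' applies the same formula to the correlation matrix instead of the
#' covariance matrix.
#'
#' @param data Complete data frame of responses (no missing values).
#' @param items Item columns to use; default all non-identifier columns.
#' @param standardized Use the correlation-matrix (standardized) variant.
#' @return A single numeric coefficient in `(-Inf, 1]`.
#' @examples
#' x <- data.frame(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
#' cronbach_alpha(x)  # duplicated items: alpha = 1
#' @export
cronbach_alpha <- function(data, items = NULL, standardized = FALSE) {
  m <- response_matrix(data, items)
  check_alpha_input(m)
  C <- if (standardized) cor(m) else cov(m)
  alpha_from_cov(C)
}

check_alpha_input <- function(m) {
  if (anyNA(m)) abort("Missing values present; impute first (impute_median()).")
  if (ncol(m) < 2L) abort("Cronbach's alpha needs at least 2 items.")
  if (nrow(m) < 3L) abort("Cronbach's alpha needs at least 3 respondents.")
  if (var(rowSums(m)) <= 0) {
    abort("Total-score variance is zero; alpha is undefined for these data.")
  }
  invisible(m)
}

# Alpha from a covariance (or correlation) matrix.
alpha_from_cov <- function(C) {
  k <- ncol(C)
  total <- sum(C)
  if (total <= 0) abort("Total-score variance is zero; alpha is undefined.")
  (k / (k - 1)) * (1 - sum(diag(C)) / total)
}

#' Confidence interval for Cronbach's alpha
#'
#' `method = "bonett"` (default) builds the interval on the
#' \eqn{\log(1-\alpha)} scale with variance \eqn{2k/\{(k-1)(n-2)\}} and
#' back-transforms; `method = "feldt"` uses the exact F-distribution
#' interval with `n - 1` and `(n - 1)(k - 1)` degrees of freedom.
#'
#' @inheritParams cronbach_alpha
#' @param level Confidence level, default `0.95`.
#' @param method `"bonett"` or `"feldt"`.
#' @return A one-row tibble: `alpha`, `lower`, `upper`, `level`, `method`,
#'   `n`, `k`.
#' @seealso [bonett_required_n()] for precision planning with the same
#'   interval.
#' @export
alpha_ci <- function(data, items = NULL, level = 0.95,
                     method = c("bonett", "feldt")) {
  method <- match.arg(method)
  m <- response_matrix(data, items)
  check_alpha_input(m)
  n <- nrow(m)
  k <- ncol(m)
  a <- alpha_from_cov(cov(m))
  if (n <= 2L) abort("Confidence intervals for alpha need n > 2.")
  if (method == "bonett") {
    hw <- bonett_log_halfwidth(k, n, level)
    lower <- 1 - (1 - a) * exp(hw)
    upper <- 1 - (1 - a) * exp(-hw)
  } else {
    p <- (1 - level) / 2
    df1 <- n - 1
    df2 <- (n - 1) * (k - 1)
    lower <- 1 - (1 - a) * qf(1 - p, df1, df2)
    upper <- 1 - (1 - a) * qf(p, df1, df2)
  }
  tibble(alpha = a, lower = lower, upper = upper,
         level = level, method = method, n = n, k = k)
}

# Half-width of the Bonett interval on the log(1 - alpha) scale.
bonett_log_halfwidth <- function(k, n, level) {
  z <- qnorm(1 - (1 - level) / 2)
  z * sqrt(2 * k / ((k - 1) * (n - 2)))
}

#' Cronbach's alpha with each item deleted in turn
#'
#' @inheritParams cronbach_alpha
#' @return A tibble with columns `item` and `alpha_if_deleted`, in item
#'   order. Items whose removal raises alpha above the full-scale value
#'   attenuate internal consistency.
#' @export
alpha_if_deleted <- function(data, items = NULL, standardized = FALSE) {
  m <- response_matrix(data, items)
  check_alpha_input(m)
  if (ncol(m) < 3L) abort("alpha_if_deleted needs at least 3 items.")
  C <- if (standardized) cor(m) else cov(m)
  vals <- vapply(seq_len(ncol(m)), function(j) {
    alpha_from_cov(C[-j, -j, drop = FALSE])
  }, numeric(1))
  tibble(item = colnames(m), alpha_if_deleted = vals)
}

#' Corrected item-total correlations
#'
#' Pearson correlation between each item and the sum of the remaining
#' items (the item's CTT discrimination). Entries below `flag_below`
#' (default 0.20, a common inclusion guideline) are flagged.
#'
#' @inheritParams cronbach_alpha
#' @param flag_below Flag threshold for weak items.
#' @return A tibble with columns `item`, `r_item_total` and `low`.
#' @export
corrected_item_total <- function(data, items = NULL, flag_below = 0.20) {
  m <- response_matrix(data, items)
  check_alpha_input(m)
  if (ncol(m) < 3L) abort("corrected_item_total needs at least 3 items.")
  total <- rowSums(m)
  vals <- vapply(seq_len(ncol(m)), function(j) {
    rest <- total - m[, j]
    if (var(m[, j]) <= 0 || var(rest) <= 0) return(NA_real_)
    cor(m[, j], rest)
  }, numeric(1))
  if (anyNA(vals)) {
    warn(paste0("Zero-variance item(s); correlation undefined for: ",
                paste(colnames(m)[is.na(vals)], collapse = ", ")))
  }
  tibble(item = colnames(m), r_item_total = vals,
         low = !is.na(vals) & vals < flag_below)
}

#' Full classical-test-theory reliability report
#'
#' Combines Cronbach's alpha with its confidence interval and the per-item
#' diagnostics (scaled mean rating, alpha-if-deleted, corrected item-total
#' correlation) into one object, mirroring the columns of a standard
#' short-form item table.
#'
#' @inheritParams alpha_ci
#' @param instrument An `instrument` (needed for scaled mean ratings).
#' @param flag_below Flag threshold passed to [corrected_item_total()].
#' @return An object of class `reliability_report`. `tidy()` returns the
#'   per-item table; `glance()` the scale-level summary.
#' @export
reliability_report <- function(data, instrument, items = NULL, level = 0.95,
                               method = c("bonett", "feldt"),
                               flag_below = 0.20) {
  inst <- instrument_subset(instrument, items)
  scale_row <- alpha_ci(data, inst$id, level = level, method = method)
  per_item <- scaled_mean_rating(data, inst) %>%
    left_join(alpha_if_deleted(data, inst$id), by = "item") %>%
    left_join(corrected_item_total(data, inst$id, flag_below = flag_below),
              by = "item")
  structure(
    list(scale = scale_row, items = per_item,
         instrument = attr(inst, "name")),
    class = "reliability_report"
  )
}

#' @export
print.reliability_report <- function(x, ...) {
  s <- x$scale
  cat("Reliability report: ", x$instrument, "\n", sep = "")
  cat(sprintf("  Cronbach's alpha %.2f (%d%% CI %.2f, %.2f; %s), n = %d, k = %d\n",
              s$alpha, round(100 * s$level), s$lower, s$upper, s$method,
              s$n, s$k))
  print(x$items, ...)
  invisible(x)
}

#' @export
tidy.reliability_report <- function(x, ...) x$items

#' @export
glance.reliability_report <- function(x, ...) x$scale
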