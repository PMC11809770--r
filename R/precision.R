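#' Half-width of the Bonett confidence interval for Cronbach's alpha
#'
#' For a planning value of alpha, `k` items and `n` respondents, the
#' interval is built on the \eqn{\log(1-\alpha)} scale with variance
#' \eqn{2k/\{(k-1)(n-2)\}} and back-transformed; its half-width on the
#' alpha scale is \eqn{(1-\alpha)\sinh(z\,\mathrm{se})}.
#'
#' @param planning_alpha Anticipated alpha, in `(0, 1)`.
#' @param k Number of items (>= 2).
#' @param n Sample size (> 2).
#' @param level Confidence level.
#' @return Half-width on the alpha scale.
#' @export
bonett_halfwidth <- function(planning_alpha, k, n, level = 0.95) {
  if (planning_alpha <= 0 || planning_alpha >= 1) {
    abort("planning_alpha must lie strictly between 0 and 1.")
  }
  if (k < 2) abort("Need k >= 2 items.")
  if (any(n <= 2)) abort("Need n > 2.")
  hw_log <- bonett_log_halfwidth(k, n, level)
  (1 - planning_alpha) * sinh(hw_log)
}

#' Required sample size for a target alpha precision (Bonett)
#'
#' Smallest `n` such that the Bonett interval for Cronbach's alpha has
#' half-width at most `half_width` on the alpha scale at the planning
#' value. When planning over a range of plausible alphas, evaluate at the
#' smallest (the interval is widest there).
#'
#' @inheritParams bonett_halfwidth
#' @param half_width Target half-width on the alpha scale (> 0).
#' @return Integer sample size (>= 3).
#' @examples
#' bonett_required_n(k = 15, planning_alpha = 0.7, half_width = 0.1)
#' @export
bonett_required_n <- function(k, planning_alpha, half_width, level = 0.95) {
  if (half_width <= 0) abort("Target half-width must be positive.")
  # closed-form inversion, then verify by direct search around it
  z <- qnorm(1 - (1 - level) / 2)
  target_log <- asinh(half_width / (1 - planning_alpha))
  n0 <- 2 + 2 * k * z^2 / ((k - 1) * target_log^2)
  n <- max(3L, floor(n0) - 2L)
  while (bonett_halfwidth(planning_alpha, k, n, level) > half_width) {
    n <- n + 1L
  }
  as.integer(n)
}

#' Fisher-z confidence interval half-width for a Pearson correlation
#'
#' Back-transformed interval `tanh(atanh(r) +/- z / sqrt(n - 3))`; the
#' half-width is `(upper - lower) / 2` on the correlation scale.
#'
#' @param r Correlation, `|r| < 1`.
#' @param n Sample size (>= 4).
#' @param level Confidence level.
#' @return Half-width on the correlation scale.
#' @examples
#' fisher_halfwidth(0.4, 135)
#' @export
fisher_halfwidth <- function(r, n, level = 0.95) {
  if (any(abs(r) >= 1)) abort("Need |r| < 1.")
  if (any(n <= 3)) abort("Need n >= 4.")
  z <- qnorm(1 - (1 - level) / 2)
  upper <- tanh(atanh(r) + z / sqrt(n - 3))
  lower <- tanh(atanh(r) - z / sqrt(n - 3))
  (upper - lower) / 2
}

#' Reliability-precision planning table
#'
#' Required sample sizes across a range of planning alphas, plus the
#' correlation precision achieved at the largest of those sizes.
#'
#' @param k Number of items.
#' @param planning_alphas Vector of anticipated alpha values.
#' @param half_width Target half-width for alpha.
#' @param level Confidence level.
#' @param r Correlation(s) at which to report Fisher-z precision.
#' @return A list of class `precision_plan` with tibbles `alpha_plan` and
#'   `correlation_precision`.
#' @export
precision_plan <- function(k, planning_alphas = c(0.7, 0.8, 0.9),
                           half_width = 0.1, level = 0.95,
                           r = c(0.3, 0.4)) {
  required_n <- vapply(planning_alphas, function(a) {
    bonett_required_n(k, a, half_width, level)
  }, integer(1))
  alpha_plan <- tibble(
    k = k,
    planning_alpha = planning_alphas,
    half_width = half_width,
    level = level,
    required_n = required_n
  )
  n_star <- max(alpha_plan$required_n)
  correlation_precision <- tibble(
    r = r, n = n_star, level = level,
    half_width = fisher_halfwidth(r, n_star, level)
  )
  structure(list(alpha_plan = alpha_plan,
                 correlation_precision = correlation_precision),
            class = "precision_plan")
}

#' @export
print.precision_plan <- function(x, ...) {
  cat("Reliability-precision plan (Bonett interval):\n")
  print(x$alpha_plan)
  cat("Fisher-z correlation precision at the planning sample size:\n")
  print(x$correlation_precision)
  invisible(x)
}

#' @export
tidy.precision_plan <- function(x, ...) x$alpha_plan
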