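#' Maximum-likelihood exploratory factor analysis
#'
#' ML factor extraction (via [stats::factanal()]) on a correlation matrix,
#' typically a polychoric matrix from [polychoric()]. The eigenvalues of
#' the input correlation matrix are reported alongside the factor
#' solution's sums of squared loadings, since "second eigenvalue"
#' unidimensionality rules can refer to either; both are exposed.
#'
#' @param x A `polychoric` object or a correlation matrix.
#' @param n_factors Number of factors to extract (>= 1).
#' @param n_obs Number of observations behind the matrix (taken from a
#'   `polychoric` object when available).
#' @param rotation Rotation: `"none"` (default) or `"varimax"`.
#' @return An object of class `efa_fit`: `loadings` (matrix),
#'   `uniquenesses`, `eigenvalues` (of the correlation matrix, descending),
#'   `factor_ss` (sums of squared loadings), `n_factors`, `converged`,
#'   `heywood` (logical: any uniqueness at the lower bound). `tidy()`
#'   returns the loadings in long form; `glance()` the fit summary.
#' @export
efa_ml <- function(x, n_factors = 1, n_obs = NULL, rotation = c("none", "varimax")) {
  rotation <- match.arg(rotation)
  if (inherits(x, "polychoric")) {
    R <- x$rho
    n_obs <- n_obs %||% x$n
  } else {
    R <- as.matrix(x)
  }
  k <- ncol(R)
  if (n_factors < 1) abort("n_factors must be >= 1.")
  max_f <- floor((2 * k + 1 - sqrt(8 * k + 1)) / 2)
  if (n_factors > max_f) {
    abort(paste0("n_factors = ", n_factors, " is inadmissible for ", k,
                 " items (max ", max_f, ")."))
  }
  if (is.null(n_obs)) abort("n_obs is required when x is a plain matrix.")
  eigenvalues <- sort(eigen(R, symmetric = TRUE, only.values = TRUE)$values,
                      decreasing = TRUE)
  fit <- tryCatch(
    factanal(covmat = R, factors = n_factors, n.obs = n_obs,
             rotation = rotation),
    error = function(e) abort(paste0("ML factor extraction failed: ",
                                     conditionMessage(e)))
  )
  L <- unclass(fit$loadings)
  heywood <- any(fit$uniquenesses <= 0.005 + 1e-8)
  if (heywood) warn("Heywood case: uniqueness at the lower bound.")
  if (!fit$converged) warn("ML factor extraction did not converge.")
  structure(
    list(loadings = L, uniquenesses = fit$uniquenesses,
         eigenvalues = eigenvalues,
         factor_ss = colSums(L^2),
         n_factors = n_factors, converged = fit$converged,
         heywood = heywood, n_obs = n_obs),
    class = "efa_fit"
  )
}

#' @export
print.efa_fit <- function(x, ...) {
  cat("ML exploratory factor analysis: ", x$n_factors, " factor(s), n = ",
      x$n_obs, "\n", sep = "")
  cat("Correlation-matrix eigenvalues:",
      paste(sprintf("%.2f", head(x$eigenvalues, 5)), collapse = ", "),
      if (length(x$eigenvalues) > 5) "...", "\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' @export
tidy.efa_fit <- function(x, ...) {
  L <- x$loadings
  tibble(
    item = rep(rownames(L), ncol(L)),
    factor = rep(colnames(L), each = nrow(L)),
    loading = as.vector(L)
  )
}

#' @export
glance.efa_fit <- function(x, ...) {
  tibble(
    n_factors = x$n_factors,
    eigenvalue_1 = x$eigenvalues[1],
    eigenvalue_2 = x$eigenvalues[2],
    converged = x$converged,
    heywood = x$heywood,
    n_obs = x$n_obs
  )
}

#' Second-eigenvalue unidimensionality check
#'
#' A scale is taken as unidimensional when the second eigenvalue of its
#' (polychoric) correlation matrix is strictly below 1. The boundary is
#' strict: a second eigenvalue of exactly 1 (e.g. an identity matrix of
#' independent items) fails the check.
#'
#' @param x An `efa_fit`, a `polychoric` object, or a numeric vector of
#'   eigenvalues in descending order.
#' @return A one-row tibble: `second_eigenvalue`, `unidimensional`.
#' @examples
#' check_unidimensionality(c(6.1, 0.98, 0.8))
#' @export
check_unidimensionality <- function(x) {
  ev <- if (inherits(x, "efa_fit")) {
    x$eigenvalues
  } else if (inherits(x, "polychoric")) {
    sort(eigen(x$rho, symmetric = TRUE, only.values = TRUE)$values,
         decreasing = TRUE)
  } else {
    as.numeric(x)
  }
  if (length(ev) < 2L) abort("Need at least two eigenvalues.")
  tibble(second_eigenvalue = ev[2L], unidimensional = ev[2L] < 1)
}
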