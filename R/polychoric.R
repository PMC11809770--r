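# Bivariate standard-normal CDF, vectorised over (h, k) for scalar rho.
# Uses Phi2(h, k; rho) = Phi(h) Phi(k) + int_0^rho phi2(h, k; t) dt with
# Gauss-Legendre quadrature on [0, rho]; the integrand is the bivariate
# normal density in t, smooth for |rho| <= 0.9995.
pbvn <- function(h, k, rho, nodes = 48L) {
  stopifnot(length(rho) == 1L, abs(rho) < 1)
  h <- pmin(pmax(h, -8.5), 8.5)
  k <- pmin(pmax(k, -8.5), 8.5)
  base <- pnorm(h) * pnorm(k)
  if (rho == 0) return(base)
  gl <- gauss_legendre(nodes)
  t_ <- rho / 2 * (gl$x + 1)
  w_ <- rho / 2 * gl$w
  add <- numeric(length(h))
  hk <- h * k
  h2k2 <- h^2 + k^2
  for (i in seq_along(t_)) {
    t1 <- t_[i]
    om <- 1 - t1^2
    add <- add + w_[i] * exp(-(h2k2 - 2 * t1 * hk) / (2 * om)) / (2 * pi * sqrt(om))
  }
  base + add
}

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch), cached.
gauss_legendre <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    i <- seq_len(n - 1L)
    b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1L)] <- b
    J[cbind(i + 1L, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    res <- list(x = rev(e$values), w = rev(2 * e$vectors[1L, ]^2))
    cache[[key]] <<- res
    res
  }
})

# Thresholds from a margin of counts: inverse-normal of cumulative
# proportions (length = categories - 1).
margin_thresholds <- function(counts) {
  p <- cumsum(counts) / sum(counts)
  qnorm(p[-length(p)])
}

# Negative log-likelihood of a two-way table under the bivariate-normal
# latent model with fixed thresholds a (rows) and b (cols).
polychoric_nll <- function(rho, tab, a, b) {
  A <- c(-Inf, a, Inf)
  B <- c(-Inf, b, Inf)
  grid_h <- rep(A, times = length(B))
  grid_k <- rep(B, each = length(A))
  FF <- matrix(pbvn(grid_h, grid_k, rho), length(A), length(B))
  P <- FF[-1, -1, drop = FALSE] - FF[-nrow(FF), -1, drop = FALSE] -
    FF[-1, -ncol(FF), drop = FALSE] + FF[-nrow(FF), -ncol(FF), drop = FALSE]
  P <- pmax(P, 1e-12)
  -sum(tab * log(P))
}

#' Polychoric correlation of two ordinal variables
#'
#' Two-step maximum likelihood: thresholds are estimated from the marginal
#' proportions by the inverse normal, then the latent correlation maximises
#' the bivariate-normal cell likelihood of the cross-table. The model
#' assumes each ordinal variable discretises a latent standard-normal
#' variable at fixed cut-points.
#'
#' @param x Either a two-way contingency table (matrix of counts) or an
#'   integer vector of codes for the first variable.
#' @param y Integer vector of codes for the second variable (ignored when
#'   `x` is a table).
#' @return A list with `rho`, `row_thresholds`, `col_thresholds`,
#'   `loglik`, `n`.
#' @examples
#' polychoric_pair(table(c(1, 1, 2, 2, 3), c(1, 2, 2, 3, 3)))
#' @export
polychoric_pair <- function(x, y = NULL) {
  tab <- if (is.null(y)) as.matrix(x) else {
    cc <- complete.cases(x, y)
    as.matrix(table(x[cc], y[cc]))
  }
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    abort(paste0("Degenerate margin: a variable has all its mass in one ",
                 "category; the polychoric correlation is undefined."))
  }
  a <- margin_thresholds(rowSums(tab))
  b <- margin_thresholds(colSums(tab))
  opt <- optimize(polychoric_nll, interval = c(-0.9995, 0.9995),
                  tab = tab, a = a, b = b, tol = 1e-6)
  list(rho = opt$minimum, row_thresholds = a, col_thresholds = b,
       loglik = -opt$objective, n = sum(tab))
}

#' Polychoric correlation matrix
#'
#' Assembles all pairwise two-step polychoric estimates. If the raw matrix
#' is not positive semi-definite it is smoothed to the nearest correlation
#' matrix (`Matrix::nearPD`) and the `smoothed` flag records that this
#' happened; the unsmoothed matrix is kept alongside.
#'
#' @param data Complete data frame of ordinal responses.
#' @param items Item columns; default all non-identifier columns.
#' @param smooth Apply PSD smoothing when needed (default `TRUE`).
#' @return An object of class `polychoric`: list with `rho` (matrix),
#'   `thresholds` (named list), `smoothed` (logical), `rho_raw`, `n`.
#'   `tidy()` returns the lower-triangle pairs as a tibble.
#' @export
polychoric <- function(data, items = NULL, smooth = TRUE) {
  m <- response_matrix(data, items)
  if (anyNA(m)) abort("Missing values present; impute first (impute_median()).")
  items <- colnames(m)
  k <- ncol(m)
  R <- diag(1, k)
  dimnames(R) <- list(items, items)
  thresholds <- setNames(vector("list", k), items)
  for (j in seq_len(k)) {
    counts <- table(m[, j])
    if (length(counts) < 2L) {
      abort(paste0("Degenerate margin for item '", items[j],
                   "': all responses in one category."))
    }
    thresholds[[j]] <- margin_thresholds(counts)
  }
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      est <- tryCatch(
        polychoric_pair(table(m[, i], m[, j])),
        error = function(e) {
          abort(paste0("Polychoric estimation failed for pair (",
                       items[i], ", ", items[j], "): ", conditionMessage(e)))
        }
      )
      R[i, j] <- R[j, i] <- est$rho
    }
  }
  smoothed <- FALSE
  R_raw <- R
  ev_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (smooth && ev_min < 0) {
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
    dimnames(R) <- dimnames(R_raw)
    smoothed <- TRUE
  }
  structure(
    list(rho = R, thresholds = thresholds, smoothed = smoothed,
         rho_raw = R_raw, n = nrow(m)),
    class = "polychoric"
  )
}

#' @export
print.polychoric <- function(x, digits = 2, ...) {
  cat("Polychoric correlation matrix (", ncol(x$rho), " items, n = ", x$n,
      if (x$smoothed) ", PSD-smoothed" else "", ")\n", sep = "")
  print(round(x$rho, digits))
  invisible(x)
}

#' @export
tidy.polychoric <- function(x, ...) {
  items <- colnames(x$rho)
  idx <- which(lower.tri(x$rho), arr.ind = TRUE)
  tibble(item1 = items[idx[, 2L]], item2 = items[idx[, 1L]],
         rho = x$rho[idx])
}
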