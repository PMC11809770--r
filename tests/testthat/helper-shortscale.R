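# Shared fixtures and independent oracles for the test suite.
# Oracles here are deliberately written from first principles, without
# reusing the package's internal computation paths.

# Ordinal one-factor test data: n x k data frame of codes 1..n_cat.
make_factor_likert <- function(n, loadings, n_cat = 5, seed = 1,
                               thresholds = NULL, prefix = "i") {
  set.seed(seed)
  k <- length(loadings)
  if (is.null(thresholds)) thresholds <- qnorm(seq_len(n_cat - 1) / n_cat)
  th <- rnorm(n)
  m <- sapply(seq_len(k), function(j) {
    z <- loadings[j] * th + sqrt(1 - loadings[j]^2) * rnorm(n)
    findInterval(z, thresholds) + 1L
  })
  colnames(m) <- sprintf("%s%02d", prefix, seq_len(k))
  out <- as.data.frame(m)
  attr(out, "theta") <- th
  out
}

# Cronbach's alpha from first principles: item variances vs total variance.
alpha_oracle <- function(m) {
  m <- as.matrix(m)
  k <- ncol(m)
  (k / (k - 1)) * (1 - sum(apply(m, 2, var)) / var(rowSums(m)))
}

# Exhaustive best subset by alpha x penalty over all non-core inclusion
# patterns; from-scratch alpha, independent of the GA code path.
exhaustive_best <- function(data, core, K = ncol(data), order = 3) {
  pool <- setdiff(names(data), core)
  nb <- length(pool)
  stopifnot(nb <= 12)
  best <- list(fitness = -Inf, items = NULL)
  for (s in 0:(2^nb - 1)) {
    sel <- c(core, pool[bitwAnd(s, 2^(seq_len(nb) - 1)) > 0])
    if (length(sel) < 2) next
    a <- alpha_oracle(data[sel])
    f <- a * (1 - (length(sel) / K)^order)
    if (f > best$fitness) best <- list(fitness = f, items = sort(sel))
  }
  best
}

# Dichotomous Rasch by direct marginal ML (nlminb on the marginal
# likelihood, no EM): an independent special-case oracle for the RSM.
rasch_mml_oracle <- function(x01) {
  x01 <- as.matrix(x01)
  nodes <- seq(-6, 6, length.out = 41)
  wq <- dnorm(nodes); wq <- wq / sum(wq)
  nll <- function(beta) {
    ll <- matrix(0, nrow(x01), length(nodes))
    for (i in seq_len(ncol(x01))) {
      p <- plogis(nodes - beta[i])
      obs <- !is.na(x01[, i])
      ll[obs, ] <- ll[obs, ] +
        outer(x01[obs, i], log(p)) + outer(1 - x01[obs, i], log(1 - p))
    }
    mx <- apply(ll, 1, max)
    -sum(mx + log(exp(ll - mx) %*% wq))
  }
  nlminb(numeric(ncol(x01)), nll)$par
}

# Model-implied covariance matrix of ordinal codes under the one-factor
# discretisation model, via bivariate-normal orthant probabilities from
# mvtnorm (independent of the package's own bivariate-normal code).
ordinal_model_cov <- function(loadings, thresholds, min_code = 1L) {
  k <- length(loadings)
  surv <- lapply(thresholds, function(t) 1 - pnorm(t))
  C <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      rho <- if (i == j) 1 else loadings[i] * loadings[j]
      ti <- thresholds[[i]]; tj <- thresholds[[j]]
      cov_ij <- 0
      for (a in seq_along(ti)) {
        for (b in seq_along(tj)) {
          joint <- if (i == j) {
            1 - pnorm(max(ti[a], tj[b]))
          } else {
            mvtnorm::pmvnorm(lower = c(ti[a], tj[b]),
                             corr = matrix(c(1, rho, rho, 1), 2))[1]
          }
          cov_ij <- cov_ij + joint - surv[[i]][a] * surv[[j]][b]
        }
      }
      C[i, j] <- C[j, i] <- cov_ij
    }
  }
  C
}
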