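test_that("identical seeds reproduce cohorts exactly; codes stay in range", {
  spec <- cohort_spec(n_respondents = 60, seed = 101)
  a <- simulate_likert(spec)
  b <- simulate_likert(spec)
  expect_identical(a, b)
  inst <- spec$instrument
  for (j in seq_len(nrow(inst))) {
    v <- a[[inst$id[j]]]
    v <- v[!is.na(v)]
    expect_true(all(v >= inst$min_code[j] &
                      v <= inst$min_code[j] + inst$n_categories[j] - 1L))
  }
  ca <- simulate_cohort(spec)
  cb <- simulate_cohort(spec)
  expect_identical(ca$responses, cb$responses)
  expect_identical(ca$covariates, cb$covariates)
})

test_that("cohort_spec validates its inputs", {
  inst <- clcf_sf()
  expect_error(cohort_spec(loadings = 1.2), "\\[0, 1\\)")
  expect_error(cohort_spec(missing_rate = 1), "missing_rate")
  expect_error(cohort_spec(covariate_correlations = c(x = 1.5)),
               "positive definite")
  bad_thresholds <- lapply(inst$n_categories, function(nc) {
    rev(qnorm(seq_len(nc - 1L) / nc))
  })
  expect_error(cohort_spec(thresholds = bad_thresholds),
               "strictly increasing")
})

test_that("zero loadings give uncorrelated items", {
  inst <- new_instrument(data.frame(id = paste0("i", 1:6), n_categories = 5))
  spec <- cohort_spec(n_respondents = 5000, instrument = inst, loadings = 0,
                      missing_rate = 0, covariate_correlations = c(),
                      group_effects = c(), seed = 102)
  d <- simulate_likert(spec)
  pc <- polychoric(d, inst$id)
  off <- pc$rho[lower.tri(pc$rho)]
  expect_lt(mean(abs(off)), 0.05)
})

test_that("simulated alpha matches the model-implied closed form", {
  inst <- clcf_sf()
  spec <- cohort_spec(n_respondents = 5000, instrument = inst, loadings = 0.7,
                      missing_rate = 0, covariate_correlations = c(),
                      group_effects = c(), seed = 103)
  d <- simulate_likert(spec)
  a_hat <- cronbach_alpha(d, inst$id)
  C <- ordinal_model_cov(spec$loadings, spec$thresholds)
  k <- ncol(C)
  a_model <- (k / (k - 1)) * (1 - sum(diag(C)) / sum(C))
  expect_lt(abs(a_hat - a_model), 0.03)
})

test_that("missingness hits its target rate", {
  spec <- cohort_spec(n_respondents = 400, missing_rate = 0.016, seed = 104)
  d <- simulate_likert(spec)
  m <- as.matrix(d[spec$instrument$id])
  expect_lt(abs(mean(is.na(m)) - 0.016), 0.005)
})

test_that("covariates hit their target trait correlations", {
  spec <- cohort_spec(n_respondents = 5000, seed = 105)
  sim <- simulate_cohort(spec)
  for (v in names(spec$covariate_correlations)) {
    r <- cor(sim$covariates[[v]], sim$truth$theta)
    expect_lt(abs(r - spec$covariate_correlations[[v]]), 0.04)
  }
})

test_that("a zero group effect yields a null standardized difference", {
  spec <- cohort_spec(n_respondents = 5000, group_effects = c(null = 0),
                      seed = 106)
  sim <- simulate_cohort(spec)
  d <- impute_median(sim$responses, spec$instrument$id)
  scores <- sum_score(d, spec$instrument)
  kg <- known_groups_test(
    data.frame(s = scores$total, g = sim$groups$null), "s", "g")
  expect_lt(abs(kg$cohens_d), 0.05)
})

test_that("RSM simulation matches closed-form category probabilities", {
  beta <- setNames(seq(-1.5, 1.5, length.out = 7), paste0("t", 1:7))
  tau <- c(-0.7, 0.7)
  persons <- rep(0.3, 2000)
  resp <- simulate_rsm(beta, tau, persons, seed = 107)
  probs <- shortscale:::rsm_probs(0.3, beta[[4]], tau)
  emp <- tabulate(resp$t4, nbins = 3) / 2000
  expect_lt(max(abs(emp - probs)), 0.02)
})

test_that("RSM limits: extreme persons and symmetric settings", {
  tau <- c(-0.5, 0.5)
  p_hi <- shortscale:::rsm_probs(30, 0, tau)
  expect_gt(p_hi[1, 3], 0.999)  # top category saturates
  # person at the item difficulty with symmetric thresholds: symmetric dist
  p_mid <- shortscale:::rsm_probs(0.4, 0.4, tau)
  expect_equal(p_mid[1, 1], p_mid[1, 3], tolerance = 1e-12)
})

test_that("missing-by-design masks propagate to NA cells", {
  beta <- setNames(c(-1, 0, 1), paste0("t", 1:3))
  mask <- matrix(FALSE, 10, 3)
  mask[1:5, 2] <- TRUE
  resp <- simulate_rsm(beta, c(-0.6, 0.6), rnorm(10), missing = mask,
                       seed = 108)
  expect_true(all(is.na(resp$t2[1:5])))
  expect_true(all(!is.na(resp$t2[6:10])))
})
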