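test_that("alpha is 1 for duplicated items and ~0 for independent items", {
  x <- data.frame(a = c(1, 2, 3, 4, 2), b = c(1, 2, 3, 4, 2))
  expect_equal(cronbach_alpha(x), 1)

  set.seed(11)
  ind <- as.data.frame(matrix(sample(1:5, 5000 * 6, replace = TRUE), 5000, 6))
  expect_lt(abs(cronbach_alpha(ind)), 0.05)
})

test_that("alpha matches the brute-force formula on random matrices", {
  set.seed(12)
  for (rep in 1:10) {
    m <- as.data.frame(matrix(sample(1:5, 40 * 5, replace = TRUE), 40, 5))
    expect_equal(cronbach_alpha(m), alpha_oracle(m), tolerance = 1e-12)
  }
})

test_that("alpha is invariant to adding a constant to an item", {
  set.seed(13)
  m <- as.data.frame(matrix(sample(1:5, 200, replace = TRUE), 40, 5))
  shifted <- m
  shifted[[2]] <- shifted[[2]] + 7
  expect_equal(cronbach_alpha(shifted), cronbach_alpha(m))
})

test_that("alpha preconditions are enforced", {
  expect_error(cronbach_alpha(data.frame(a = 1:5)), "at least 2 items")
  expect_error(cronbach_alpha(data.frame(a = 1:2, b = 2:1)), "3 respondents")
  expect_error(cronbach_alpha(data.frame(a = c(1, 2, 3), b = c(3, 2, 1))),
               "variance is zero")
  expect_error(cronbach_alpha(data.frame(a = c(1, NA, 3), b = c(1, 2, 3))),
               "[Ii]mpute")
})

test_that("Bonett and Feldt intervals bracket the point estimate and shrink with n", {
  d <- make_factor_likert(135, rep(0.5, 15), seed = 14)
  for (method in c("bonett", "feldt")) {
    ci <- alpha_ci(d, method = method)
    expect_true(ci$lower <= ci$alpha && ci$alpha <= ci$upper)
    expect_lt(ci$upper, 1)
  }
  big <- make_factor_likert(1000, rep(0.5, 15), seed = 15)
  w_small <- with(alpha_ci(d), upper - lower)
  w_big <- with(alpha_ci(big), upper - lower)
  expect_lt(w_big, w_small)
})

test_that("Bonett half-width at k=15, n=135, alpha=0.7 is within +/-0.1", {
  expect_lte(bonett_halfwidth(0.7, k = 15, n = 135), 0.1)
})

test_that("Bonett 95% interval covers the true alpha in >=93% of replications", {
  # parallel continuous items with true alpha 0.8: r = a/(k-(k-1)a)
  k <- 15; n <- 135; a_true <- 0.8
  r <- a_true / (k - (k - 1) * a_true)
  lam <- sqrt(r)
  set.seed(16)
  covered <- logical(1000)
  for (i in seq_along(covered)) {
    th <- rnorm(n)
    m <- lam * th + sqrt(1 - r) * matrix(rnorm(n * k), n, k)
    ci <- alpha_ci(as.data.frame(m))
    covered[i] <- ci$lower <= a_true && a_true <= ci$upper
  }
  expect_gte(mean(covered), 0.93)
})

test_that("alpha_if_deleted equals from-scratch recomputation per item", {
  d <- make_factor_likert(80, c(0.7, 0.6, 0.5, 0.6, 0.7), seed = 17)
  aid <- alpha_if_deleted(d)
  for (j in seq_along(d)) {
    expect_equal(aid$alpha_if_deleted[j], alpha_oracle(d[-j]),
                 tolerance = 1e-12)
  }
  dup3 <- data.frame(a = c(1, 3, 2, 4), b = c(1, 3, 2, 4), c = c(1, 3, 2, 4))
  expect_equal(alpha_if_deleted(dup3)$alpha_if_deleted, rep(1, 3))
})

test_that("deleting a pure-noise item raises alpha above the full scale", {
  d <- make_factor_likert(400, c(rep(0.7, 6), 0), seed = 18)
  full <- cronbach_alpha(d)
  aid <- alpha_if_deleted(d)
  expect_gt(aid$alpha_if_deleted[7], full)
})

test_that("corrected item-total correlations behave and flag weak items", {
  set.seed(19)
  rest <- matrix(sample(1:5, 60 * 4, replace = TRUE), 60, 4)
  d <- as.data.frame(cbind(rest, rowSums(rest)))
  names(d) <- c(paste0("i", 1:4), "dup")
  cit <- corrected_item_total(d)
  expect_equal(cit$r_item_total[cit$item == "dup"], 1)

  noisy <- make_factor_likert(5000, c(rep(0.7, 5), 0), seed = 20)
  cit2 <- corrected_item_total(noisy)
  expect_lt(abs(cit2$r_item_total[6]), 0.05)
  expect_true(cit2$low[6])
  expect_false(any(cit2$low[1:5]))

  # from-scratch oracle: correlation with the rest-score
  d3 <- make_factor_likert(50, c(0.6, 0.5, 0.7, 0.4), seed = 21)
  cit3 <- corrected_item_total(d3)
  for (j in seq_along(d3)) {
    expect_equal(cit3$r_item_total[j],
                 cor(d3[[j]], rowSums(d3[-j])), tolerance = 1e-12)
  }
})

test_that("reliability_report assembles the item table and scale summary", {
  inst <- clcf_sf()
  d <- impute_median(simulate_likert(cohort_spec(seed = 22)), inst$id)
  rep <- reliability_report(d, inst)
  items <- tidy(rep)
  expect_equal(nrow(items), 15L)
  expect_named(items, c("item", "scaled_mean_rating", "alpha_if_deleted",
                        "r_item_total", "low"))
  scale <- glance(rep)
  expect_true(scale$lower <= scale$alpha && scale$alpha <= scale$upper)
  expect_equal(scale$k, 15L)
})
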