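test_that("perfect association gives coefficient 1 under either method", {
  d <- data.frame(x = c(1.2, 3.4, 2.2, 5.1, 4.4, 0.7), y = NA)
  d$y <- d$x
  expect_equal(cor_validity(d, "x", "y")$estimate, 1)
  # skewed x with strictly monotone nonlinear y: Spearman selected, rho = 1
  set.seed(91)
  sk <- data.frame(x = rexp(300)^2)
  sk$y <- log1p(sk$x)
  res <- cor_validity(sk, "x", "y")
  expect_equal(res$method, "spearman")
  expect_equal(res$estimate, 1)
  expect_match(res$rationale, "Shapiro-Wilk")
})

test_that("the normality gate recovers a planted bivariate-normal correlation", {
  set.seed(92)
  n <- 5000
  x <- rnorm(n)
  y <- 0.45 * x + sqrt(1 - 0.45^2) * rnorm(n)
  res <- cor_validity(data.frame(x = x, y = y), "x", "y")
  expect_lt(abs(res$pearson_r - 0.45), 0.04)
  # both coefficients are retained regardless of the gate
  expect_true(is.finite(res$spearman_rho))
  expect_true(res$n == n)
})

test_that("Spearman is invariant under monotone transforms", {
  set.seed(93)
  x <- rexp(200)
  y <- x + rexp(200)
  r1 <- cor_validity(data.frame(x = x, y = y), "x", "y")$spearman_rho
  r2 <- cor_validity(data.frame(x = exp(x), y = y^3), "x", "y")$spearman_rho
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("degenerate correlation inputs are refused", {
  expect_error(cor_validity(data.frame(x = rep(1, 10), y = rnorm(10)),
                            "x", "y"), "Constant")
  expect_error(cor_validity(data.frame(x = 1:3, y = 3:1), "x", "y"),
               "at least 4")
})

test_that("known-groups test matches hand-worked values", {
  d <- data.frame(s = c(1, 2, 3, 4, 5, 6),
                  g = rep(c("a", "b"), each = 3))
  kg <- known_groups_test(d, "s", "g")
  # groups {1,2,3} vs {4,5,6}: difference 3, pooled SD 1, d = 3
  expect_equal(kg$mean_difference, 3)
  expect_equal(kg$cohens_d, 3)
  expect_true(kg$conf_low <= 3 && 3 <= kg$conf_high)
  # identical distributions: zero difference and zero d
  same <- data.frame(s = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  kg0 <- known_groups_test(same, "s", "g")
  expect_equal(kg0$mean_difference, 0)
  expect_equal(kg0$cohens_d, 0)
})

test_that("Welch and pooled variants agree on the sign and the difference", {
  set.seed(94)
  d <- data.frame(s = c(rnorm(40, 0, 1), rnorm(25, 0.8, 2)),
                  g = rep(c(0, 1), c(40, 25)))
  pooled <- known_groups_test(d, "s", "g", var_equal = TRUE)
  welch <- known_groups_test(d, "s", "g", var_equal = FALSE)
  expect_equal(pooled$mean_difference, welch$mean_difference)
  expect_equal(sign(pooled$t_statistic), sign(welch$t_statistic))
  expect_true(all(c(pooled$p_value, welch$p_value) >= 0 &
                    c(pooled$p_value, welch$p_value) <= 1))
})

test_that("a planted standardized shift is recovered at scale", {
  set.seed(95)
  n <- 5000
  g <- rep(0:1, each = n)
  s <- rnorm(2 * n) + 0.37 * g
  kg <- known_groups_test(data.frame(s = s, g = g), "s", "g")
  expect_lt(abs(kg$cohens_d - 0.37), 0.06)
  expect_error(known_groups_test(data.frame(s = 1:3, g = c(1, 2, 2)),
                                 "s", "g"), "at least 2")
})

test_that("the battery runs each comparison on its own complete cases", {
  set.seed(96)
  n <- 200
  th <- rnorm(n)
  d <- data.frame(
    score = th,
    bdi = 0.5 * th + rnorm(n),
    stai = 0.4 * th + rnorm(n),
    unwell = rbinom(n, 1, 0.5)
  )
  d$bdi[1:60] <- NA  # differing availability, as with real covariates
  rep <- validity_battery(d, "score", c("bdi", "stai"), "unwell")
  expect_equal(rep$correlations$n[rep$correlations$measure == "bdi"], 140L)
  expect_equal(rep$correlations$n[rep$correlations$measure == "stai"], 200L)
  expect_equal(nrow(rep$group_comparisons), 1L)
  td <- tidy(rep)
  expect_setequal(td$analysis, c("correlation", "known_groups"))
  # too-few pairs: skipped with a warning, not an error
  d$rare <- NA_real_
  d$rare[1:3] <- rnorm(3)
  expect_warning(rep2 <- validity_battery(d, "score", "rare", character()),
                 "rare")
  expect_equal(nrow(rep2$correlations), 0L)
  # misaligned column names are a pre-flight error naming the column
  expect_error(validity_battery(d, "score", "missing_col", character()),
               "missing_col")
})
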