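test_that("the length penalty follows 1 - (k/K)^order with clamping", {
  expect_equal(ga_penalty(0, 46), 1)
  expect_equal(ga_penalty(46, 46), 0)
  expect_equal(ga_penalty(15, 46, order = 3), 1 - (15 / 46)^3)
  expect_equal(ga_penalty(15, 46), 0.9653263, tolerance = 1e-6)
  for (ord in 2:5) {
    p <- ga_penalty(0:20, 20, order = ord)
    expect_true(all(p >= 0 & p <= 1))
    expect_true(all(diff(p) < 0))  # longer subsets always pay more
  }
  expect_error(ga_penalty(5, 4), "0 <= k <= K")
  expect_error(ga_penalty(3, 10, order = 6), "order")
  # literal-difference audit variant clamps into [0, 1]: with k < K an odd
  # order gives 1 - (negative)^3 > 1 -> 1; an even order gives a negative
  # value -> 0. Neither discriminates length, which is why it is audit-only.
  expect_equal(ga_penalty(10, 46, variant = "raw"), 1)
  expect_equal(ga_penalty(10, 46, order = 2, variant = "raw"), 0)
  expect_equal(ga_penalty(46, 46, variant = "raw"), 1)
})

test_that("fitness is alpha x penalty and enforces core membership", {
  d <- make_factor_likert(120, rep(0.6, 8), seed = 31)
  sub <- names(d)[1:5]
  f <- ga_fitness(d, sub, core = "i01")
  expect_equal(f$fitness, f$alpha * f$penalty)
  expect_equal(f$alpha, alpha_oracle(d[sub]), tolerance = 1e-12)
  expect_equal(f$penalty, 1 - (5 / 8)^3)
  expect_error(ga_fitness(d, names(d)[2:5], core = "i01"),
               "missing core item")
  # full pool: penalty zero regardless of alpha
  expect_equal(ga_fitness(d, names(d))$fitness, 0)
  # equal-size subsets rank by alpha alone
  f1 <- ga_fitness(d, names(d)[1:4])
  f2 <- ga_fitness(d, names(d)[5:8])
  expect_equal(f1$fitness > f2$fitness, f1$alpha > f2$alpha)
})

test_that("evolve finds the exhaustive optimum on a small pool", {
  d <- make_factor_likert(300, runif(12, 0.1, 0.8), seed = 32)
  core <- c("i01", "i02")
  oracle <- exhaustive_best(d, core)
  fit <- ga_evolve(d, core = core, params = ga_params(seed = 33))
  expect_equal(fit$best$fitness, oracle$fitness, tolerance = 1e-12)
  expect_equal(fit$best$items[[1]], oracle$items)
})

test_that("core items are locked in and the trace is non-decreasing", {
  d <- make_factor_likert(150, runif(10, 0, 0.8), seed = 34)
  core <- c("i03", "i07")
  fit <- ga_evolve(d, core = core, params = ga_params(seed = 35))
  expect_true(all(core %in% fit$best$items[[1]]))
  expect_true(all(diff(fit$trace$best_fitness) >= 0))
  # stagnation contract: trace tail is flat for >= stagnation_limit gens
  tail_len <- fit$params$stagnation_limit
  tail_vals <- utils::tail(fit$trace$best_fitness, tail_len)
  expect_equal(max(tail_vals) - min(tail_vals), 0)
})

test_that("evolve is reproducible and rejects degenerate pools", {
  d <- make_factor_likert(100, rep(0.5, 6), seed = 36)
  f1 <- ga_evolve(d, params = ga_params(seed = 37))
  f2 <- ga_evolve(d, params = ga_params(seed = 37))
  expect_identical(f1$best, f2$best)
  dead <- d
  dead$i01 <- 3
  expect_error(ga_evolve(dead), "Zero-variance")
})

test_that("multi-start reports agreement honestly", {
  d <- make_factor_likert(200, c(rep(0.7, 5), rep(0, 5)), seed = 38)
  ms <- ga_multi_start(d, params = ga_params(), n_starts = 3, seed = 39)
  expect_s3_class(ms, "ga_multi")
  expect_equal(nrow(ms$runs), 3L)
  expect_type(ms$agreement, "logical")
  # identical seeds give identical solutions
  p <- ga_params(seed = 40)
  a <- ga_evolve(d, params = p)
  b <- ga_evolve(d, params = p)
  expect_identical(a$best$items, b$best$items)
  expect_error(ga_multi_start(d, n_starts = 1), "at least 2")
})

test_that("ga_params validates its ranges", {
  expect_error(ga_params(cull_fraction = 0), "cull_fraction")
  expect_error(ga_params(mutation_rate = 1.2), "mutation_rate")
  expect_error(ga_params(stagnation_limit = 0), "stagnation_limit")
  expect_error(ga_params(penalty_order = 7), "penalty_order")
})
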