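test_that("packaged CLCF-SF definition has the published structure", {
  inst <- clcf_sf()
  expect_s3_class(inst, "instrument")
  expect_equal(nrow(inst), 15L)
  expect_equal(sum(inst$core), 5L)
  expect_equal(sum(inst$n_categories == 5L), 13L)
  expect_equal(sum(inst$n_categories == 4L), 2L)
  expect_true(all(inst$min_code == 1L))
})

test_that("instrument validation rejects malformed definitions", {
  expect_s3_class(new_instrument(data.frame(id = "only", n_categories = 4)),
                  "instrument")
  expect_error(new_instrument(data.frame(id = c("a", "a"),
                                         n_categories = c(5, 5))),
               "Duplicated item id.*a")
  expect_error(new_instrument(data.frame(id = "a", n_categories = 1)),
               "n_categories")
  expect_error(new_instrument(data.frame(id = "a", n_categories = 5,
                                         bogus = 1)),
               "Unknown instrument fields")
  expect_error(new_instrument(data.frame(id = character(),
                                         n_categories = integer())),
               "at least one item")
})

test_that("sum_score matches hand-worked totals and scoring extremes", {
  inst <- clcf_sf()
  lowest <- as.data.frame(as.list(setNames(inst$min_code, inst$id)))
  highest <- as.data.frame(as.list(setNames(
    inst$min_code + inst$n_categories - 1L, inst$id)))
  expect_equal(sum_score(lowest, inst)$total, 15)
  expect_equal(sum_score(highest, inst)$total, 73)

  three <- new_instrument(data.frame(id = c("a", "b", "c"), n_categories = 5))
  expect_equal(sum_score(data.frame(a = 2, b = 3, c = 4), three)$total, 9)

  # missing values are refused with a pointer to imputation
  expect_error(sum_score(data.frame(a = NA, b = 3, c = 4), three),
               "[Ii]mpute")
  # out-of-range codes are rejected
  expect_error(sum_score(data.frame(a = 7, b = 3, c = 4), three),
               "Out-of-range")
})

test_that("reverse-keyed items are reflected about the scale midpoint", {
  inst <- new_instrument(data.frame(id = c("a", "b"), n_categories = 5,
                                    reverse = c(FALSE, TRUE)))
  # b = 1 reflects to 5, b = 5 to 1
  expect_equal(sum_score(data.frame(a = 1, b = 1), inst)$total, 1 + 5)
  expect_equal(sum_score(data.frame(a = 1, b = 5), inst)$total, 1 + 1)
})

test_that("score_range equals exhaustive enumeration on a random instrument", {
  set.seed(42)
  inst <- new_instrument(data.frame(
    id = paste0("q", 1:6),
    n_categories = sample(2:4, 6, replace = TRUE),
    min_code = sample(0:1, 6, replace = TRUE)
  ))
  grid <- expand.grid(lapply(seq_len(6), function(j) {
    inst$min_code[j] + 0:(inst$n_categories[j] - 1L)
  }))
  totals <- rowSums(grid)
  rng <- score_range(inst)
  expect_equal(rng$min_total, min(totals))
  expect_equal(rng$max_total, max(totals))
  expect_error(score_range(inst, character(0)), "Empty")
})

test_that("sum_score is monotone in any single response and bounded by score_range", {
  set.seed(7)
  inst <- new_instrument(data.frame(id = paste0("q", 1:5),
                                    n_categories = c(5, 5, 4, 3, 5)))
  d <- as.data.frame(sapply(seq_len(5), function(j) {
    sample(inst$n_categories[j], 20, replace = TRUE)
  }))
  names(d) <- inst$id
  rng <- score_range(inst)
  totals <- sum_score(d, inst)$total
  expect_true(all(totals >= rng$min_total & totals <= rng$max_total))
  # bump one response one category up: total increases by exactly 1
  d2 <- d
  j <- which(d2[3, ] < inst$n_categories)[1]
  d2[3, j] <- d2[3, j] + 1
  expect_equal(sum_score(d2, inst)$total[3], totals[3] + 1)
})

test_that("treatment_count_score counts distinct nonzero treatments", {
  d <- data.frame(a = c(0, 1, 2), b = c(0, 0, 0), c = c(0, 1, 1))
  expect_equal(treatment_count_score(d)$n_treatments, c(0L, 2L, 2L))
  expect_equal(treatment_count_score(data.frame(a = 1, b = 0, c = 1, d = 1))$n_treatments, 3L)
  expect_error(treatment_count_score(data.frame(a = -1)), "nonnegative")
})

test_that("instrument files round-trip through read_instrument", {
  inst <- clcf_sf()
  tmp <- tempfile(fileext = ".csv")
  readr::write_csv(as_tibble(inst), tmp)
  again <- read_instrument(tmp)
  expect_equal(as.data.frame(again), as.data.frame(inst), ignore_attr = TRUE)
})
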