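test_that("max_percentage_error matches direct arithmetic", {
  expect_identical(max_percentage_error(c(1, 2), c(1, 2)), 0)
  expect_equal(max_percentage_error(c(1.05, 1.9), c(1.0, 2.0)), 5)
  ref <- c(0.9, 1.3, 1.8)
  expect_equal(max_percentage_error(1.1 * ref, ref), 10, tolerance = 1e-12)
  expect_error(max_percentage_error(c(1, 2), c(1, 0)),
               class = "icv_input_error")
})

test_that("m = 1 pipeline degenerates to ICC 1, MPE 0, spread 0", {
  co <- small_cohort("AC", n = 4, seed = 3)
  draws <- run_randomized_reliability(co, periods = 1, n_reps = 25, seed = 9)
  expect_true(all(draws$icc == 1))
  expect_true(all(draws$mpe_percent == 0))
  curve <- summarize_curve(draws)
  expect_identical(curve$icc_spread, 0)
  expect_identical(curve$icc_p5, 1)
})

test_that("reliability draws are deterministic given the seed", {
  co <- small_cohort("AD", n = 3, seed = 5)
  d1 <- run_randomized_reliability(co, periods = c(2, 5), n_reps = 40,
                                   seed = 77)
  d2 <- run_randomized_reliability(co, periods = c(2, 5), n_reps = 40,
                                   seed = 77)
  expect_identical(d1, d2)
  d3 <- run_randomized_reliability(co, periods = c(2, 5), n_reps = 40,
                                   seed = 78)
  expect_false(identical(d1$icc, d3$icc))
})

test_that("reliability accepts mask lists and validates the cohort", {
  masks <- lapply(1:3, random_mask, dims = c(8L, 8L, 30L),
                  spacing = c(1, 1, 1))
  draws <- run_randomized_reliability(masks, periods = 2, n_reps = 10,
                                      seed = 1)
  expect_equal(nrow(draws), 10)
  expect_true(all(draws$icc <= 1))
  expect_error(run_randomized_reliability(masks[1], periods = 2,
                                          n_reps = 5, seed = 1),
               class = "icv_input_error")
})

test_that("smoother cohorts keep higher ICC at a fixed period", {
  # roughness ordering, checked over seeded replicates
  wins <- 0L
  for (r in 1:5) {
    smooth <- generate_cohort(
      phantom_spec(c(40, 35, 32), 0, 0L, grid_shape = c(112L, 112L, 112L),
                   target_icv_mean = 0.1874, target_icv_sd = 0.015),
      6, "S", 100 + r, keep_masks = FALSE)
    rough <- generate_cohort(
      phantom_spec(c(40, 35, 32), 6, 12L, grid_shape = c(112L, 112L, 112L),
                   target_icv_mean = 0.1874, target_icv_sd = 0.015),
      6, "R", 100 + r, keep_masks = FALSE)
    ds <- run_randomized_reliability(smooth, periods = 6, n_reps = 150,
                                     seed = r)
    dr <- run_randomized_reliability(rough, periods = 6, n_reps = 150,
                                     seed = r)
    p5s <- quantile(ds$icc, 0.05, names = FALSE)
    p5r <- quantile(dr$icc, 0.05, names = FALSE)
    if (p5s > p5r) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("summarize_curve computes order-statistic percentiles", {
  draws <- data.frame(m = 2L, rep = 1:300,
                      icc = rep(c(0.98, 0.99, 1.00), each = 100),
                      mpe_percent = rep(c(2, 1, 0), each = 100))
  curve <- summarize_curve(draws)
  expect_equal(curve$icc_p50, 0.99)
  expect_equal(curve$icc_p5, 0.98)
  expect_equal(curve$icc_p95, 1.00)
  expect_equal(curve$icc_spread, 0.02)
  expect_equal(curve$mpe_min, 0)
  expect_equal(curve$mpe_max, 2)
  # percentile monotonicity on random draws
  set.seed(3)
  rnd <- data.frame(m = rep(c(2L, 5L), each = 50), rep = rep(1:50, 2),
                    icc = runif(100, 0.9, 1), mpe_percent = runif(100, 0, 5))
  cu <- summarize_curve(rnd)
  expect_true(all(cu$icc_p5 <= cu$icc_p25 & cu$icc_p25 <= cu$icc_p50 &
                  cu$icc_p50 <= cu$icc_p75 & cu$icc_p75 <= cu$icc_p95))
  expect_true(all(cu$icc_spread >= 0))
  expect_error(summarize_curve(data.frame()), class = "icv_input_error")
})

test_that("guideline extraction follows the contiguous-from-smallest rule", {
  curve <- data.frame(m = 1:5,
                      icc_p5 = c(1.0, 0.999, 0.992, 0.989, 0.991),
                      icc_spread = c(0.001, 0.004, 0.006, 0.01, 0.012),
                      n_reps = 100L)
  g <- guideline_max_period(curve, "confidence_icc", icc_threshold = 0.99,
                            slice_spacing = 1.5)
  expect_true(g$satisfied)
  expect_identical(g$max_period_slices, 3L)
  expect_equal(g$max_period_mm, 4.5)

  g2 <- guideline_max_period(curve, "tight_spread", spread_max = 0.005,
                             slice_spacing = 1)
  expect_identical(g2$max_period_slices, 2L)

  all_pass <- data.frame(m = c(2, 5, 9), icc_p5 = 1, icc_spread = 0,
                         n_reps = 10L)
  expect_identical(
    guideline_max_period(all_pass, "confidence_icc")$max_period_slices, 9)

  none <- data.frame(m = 2:4, icc_p5 = c(0.9, 0.95, 0.99),
                     icc_spread = 0.1, n_reps = 10L)
  g3 <- guideline_max_period(none, "confidence_icc")
  expect_false(g3$satisfied)
  expect_true(is.na(g3$max_period_slices))
})

test_that("raising the ICC threshold never lengthens the guideline", {
  set.seed(21)
  curve <- data.frame(m = 2:12,
                      icc_p5 = sort(runif(11, 0.97, 1), decreasing = TRUE),
                      icc_spread = 0.001, n_reps = 50L)
  periods <- vapply(c(0.97, 0.98, 0.99, 0.995, 0.999), function(th) {
    g <- guideline_max_period(curve, "confidence_icc", icc_threshold = th)
    if (g$satisfied) g$max_period_slices else 0L
  }, integer(1))
  expect_true(all(diff(periods) <= 0))
})

test_that("shared-start mode uses one offset per repetition", {
  co <- small_cohort("AC", n = 4, seed = 2)
  # with shared starts and identical geometry the per-rep estimates of a
  # duplicated subject are identical; verify via determinism of draws only
  d <- run_randomized_reliability(co, periods = 10, n_reps = 30, seed = 4,
                                  shared_starts = TRUE)
  expect_equal(nrow(d), 30)
  expect_true(all(d$icc <= 1))
})
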