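test_that("phantom_spec enforces geometry invariants", {
  expect_error(phantom_spec(c(90, 70, 60), grid_shape = c(96L, 192L, 192L)),
               class = "icv_geometry_error")
  expect_error(phantom_spec(c(40, 30, 20), roughness_amplitude = 12,
                            grid_shape = c(128L, 128L, 128L)),
               class = "icv_geometry_error")
  expect_error(phantom_spec(c(40, -30, 20)), class = "icv_input_error")
  s <- phantom_spec(c(40, 32, 28), grid_shape = c(96L, 96L, 96L))
  expect_s3_class(s, "phantom_spec")
})

test_that("smooth phantom recovers the analytic ellipsoid volume", {
  semi <- c(40, 32, 28)
  analytic <- 4 / 3 * pi * prod(semi) / 1e6
  spec <- phantom_spec(semi, grid_shape = c(96L, 96L, 96L))
  ph <- generate_phantom(spec, subject_seed = 1)
  expect_lt(abs(icv_from_mask(ph) - analytic) / analytic, 0.01)
  # the voxelisation agrees with an independent plain-R count
  expect_identical(sum(ph$occupancy),
                   oracle_ellipsoid_count(semi, c(96, 96, 96), c(1, 1, 1)))
})

test_that("phantom generation is deterministic and seed-sensitive", {
  spec <- phantom_preset("AD", grid_shape = c(96L, 96L, 96L),
                         spacing = c(2, 2, 2))
  a <- generate_phantom(spec, subject_seed = 12)
  b <- generate_phantom(spec, subject_seed = 12)
  expect_identical(a$occupancy, b$occupancy)
  c <- generate_phantom(spec, subject_seed = 13)
  expect_false(identical(a$occupancy, c$occupancy))
})

test_that("isotropic x2 scaling multiplies the voxel volume by ~8", {
  s1 <- phantom_spec(c(20, 16, 14), grid_shape = c(96L, 96L, 96L),
                     spacing = c(0.5, 0.5, 0.5))
  s2 <- phantom_spec(c(40, 32, 28), grid_shape = c(192L, 192L, 192L),
                     spacing = c(0.5, 0.5, 0.5))
  v1 <- icv_from_mask(generate_phantom(s1, 1))
  v2 <- icv_from_mask(generate_phantom(s2, 1))
  expect_lt(abs(v2 / v1 - 8), 0.08)
})

test_that("rough phantoms stay a single 26-connected component", {
  for (seed in c(2, 9)) {
    spec <- phantom_preset("AD", grid_shape = c(96L, 96L, 96L),
                           spacing = c(2, 2, 2))
    ph <- generate_phantom(spec, subject_seed = seed)
    expect_identical(
      icvsampler:::count_components26(ph$occupancy, dim(ph$occupancy)), 1L)
    expect_true(all(ph$occupancy %in% c(0L, 1L)))
  }
})

test_that("cohorts hit the target ICV distribution and are reproducible", {
  co <- generate_cohort(phantom_preset("AC", grid_shape = c(96L, 96L, 96L),
                                       spacing = c(2, 2, 2)),
                        n_subjects = 2, "AC", master_seed = 4)
  expect_equal(nrow(co$subjects), 2)
  expect_false(anyDuplicated(co$subjects$subject_id) > 0)

  co2 <- generate_cohort(phantom_preset("AC", grid_shape = c(96L, 96L, 96L),
                                        spacing = c(2, 2, 2)),
                         n_subjects = 2, "AC", master_seed = 4)
  expect_identical(co$subjects, co2$subjects)
  expect_error(generate_cohort(phantom_preset("AC"), 1, "AC", 1),
               class = "icv_input_error")

  # large-sample mean within 3 SE of the group target (coarse grid)
  big <- generate_cohort(phantom_preset("AC", grid_shape = c(96L, 96L, 96L),
                                        spacing = c(2, 2, 2)),
                         200, "AC", 42, keep_masks = FALSE)
  se <- 0.14444 / sqrt(200)
  expect_lt(abs(mean(big$subjects$true_icv_l) - 1.4609), 3 * se)
  # demographics follow the preset: 9/11 female, ages near 71
  expect_equal(sum(big$subjects$sex == "F"), round(200 * 9 / 11))
  expect_lt(abs(mean(big$subjects$age) - 71), 3 * 6.21 / sqrt(200))
})

test_that("zero-jitter tracing is the identity; jitter moves the boundary", {
  co <- small_cohort("AC", n = 2, seed = 6, keep_masks = TRUE)
  m <- co$masks[[1]]
  expect_identical(simulate_operator_tracing(m, operator_model(0), 1), m)
  traced <- simulate_operator_tracing(m, operator_model(0.5), 1)
  expect_false(identical(traced$occupancy, m$occupancy))
  # tracing is reproducible and operator-specific
  t2 <- simulate_operator_tracing(m, operator_model(0.5), 1)
  expect_identical(traced$occupancy, t2$occupancy)
  t3 <- simulate_operator_tracing(m, operator_model(0.5, seed_offset = 1), 1)
  expect_false(identical(traced$occupancy, t3$occupancy))
})

test_that("calibrated jitter lands tracing error at the manual-rater scale", {
  co <- generate_cohort(phantom_preset("AC"), 10, "AC", 15,
                        keep_masks = TRUE)
  cal <- calibrate_operator_jitter(co$masks, target_mrpad = 0.008,
                                   candidates = c(0.005, 0.02, 0.08),
                                   seed = 3)
  expect_true(cal$achieved_mrpad >= 0.001 && cal$achieved_mrpad <= 0.02)
  expect_true(cal$boundary_jitter_sd %in% c(0.005, 0.02, 0.08))
})

test_that("two equal-jitter operators are statistically indistinguishable", {
  nonsig <- 0L
  for (r in 1:10) {
    co <- generate_cohort(
      phantom_preset("AC", grid_shape = c(128L, 128L, 128L),
                     spacing = c(1.5, 1.5, 1.5)),
      8, "AC", 500 + r, keep_masks = TRUE)
    op1 <- operator_model(0.02, 1)
    op2 <- operator_model(0.02, 2)
    v1 <- vapply(seq_along(co$masks), function(i)
      icv_from_mask(simulate_operator_tracing(co$masks[[i]], op1,
                                              co$subjects$seed[i])),
      numeric(1))
    v2 <- vapply(seq_along(co$masks), function(i)
      icv_from_mask(simulate_operator_tracing(co$masks[[i]], op2,
                                              co$subjects$seed[i])),
      numeric(1))
    expect_false(identical(v1, v2))
    if (paired_t_test(v1, v2)$p_value > 0.05) nonsig <- nonsig + 1L
  }
  expect_gte(nonsig, 9L)
})

test_that("tool simulation follows the bias/noise contract", {
  truth <- c(1.3, 1.45, 1.6)
  expect_identical(simulate_tool_icv(truth, tool_model("id"), 1), truth)
  expect_equal(mrpad(simulate_tool_icv(truth, tool_model("x", 2.77), 1),
                     truth), 177, tolerance = 1e-12)
  expect_equal(mrpad(simulate_tool_icv(truth, tool_model("x", 0.9), 1),
                     truth), 10, tolerance = 1e-12)
  noisy <- simulate_tool_icv(truth, tool_model("n", 1, 0.05), 2)
  expect_identical(noisy, simulate_tool_icv(truth, tool_model("n", 1, 0.05), 2))
  expect_false(identical(noisy,
                         simulate_tool_icv(truth, tool_model("n", 1, 0.05), 3)))
  expect_true(all(noisy > 0))
  expect_error(simulate_tool_icv(c(1, -1), tool_model("x"), 1),
               class = "icv_input_error")
  expect_error(tool_model("x", mult_bias = 0), class = "icv_input_error")
})
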