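# Independent oracles and small fixture builders used across the suite.

# Brute-force two-way ANOVA sums of squares for n targets x 2 raters,
# written with explicit loops over the data table (independent of the
# package's closed-form path).
oracle_icc_agreement <- function(x, y) {
  n <- length(x)
  tab <- rbind(x, y)  # 2 raters x n targets
  grand <- mean(tab)
  ss_row <- 0  # targets
  for (j in seq_len(n)) ss_row <- ss_row + 2 * (mean(tab[, j]) - grand)^2
  ss_col <- 0  # raters
  for (i in 1:2) ss_col <- ss_col + n * (mean(tab[i, ]) - grand)^2
  ss_tot <- sum((tab - grand)^2)
  ss_err <- ss_tot - ss_row - ss_col
  msr <- ss_row / (n - 1)
  msc <- ss_col / 1
  mse <- ss_err / (n - 1)
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}

# Brute-force voxel-count volume of an ellipsoid (centre-inside rule) on a
# (i + 0.5) * h voxel-centre lattice, matching the phantom's convention but
# computed by plain R vector arithmetic.
oracle_ellipsoid_count <- function(semi, grid, spacing) {
  centre <- grid * spacing / 2
  x <- ((seq_len(grid[1]) - 0.5) * spacing[1] - centre[1]) / semi[1]
  y <- ((seq_len(grid[2]) - 0.5) * spacing[2] - centre[2]) / semi[2]
  z <- ((seq_len(grid[3]) - 0.5) * spacing[3] - centre[3]) / semi[3]
  q <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  sum(q <= 1)
}

# Random small binary mask with random spacing (reproducible).
random_mask <- function(seed, dims = c(12L, 12L, 24L), p = 0.4,
                        spacing = NULL) {
  set.seed(seed)
  if (is.null(spacing)) spacing <- runif(3, 0.5, 2)
  occ <- array(as.integer(runif(prod(dims)) < p), dims)
  mask_volume(occ, spacing = spacing)
}

# Mask with a constant 10 x 10 mm^2 cross-section over `nslices` slices
# (1 mm isotropic), the worked subsampling example.
constant_profile_mask <- function(nslices = 10L, first_slice = 6L) {
  occ <- array(0L, c(16L, 16L, first_slice + nslices + 4L))
  occ[4:13, 4:13, first_slice:(first_slice + nslices - 1L)] <- 1L
  mask_volume(occ, spacing = c(1, 1, 1))
}

# Small, fast phantom cohort for pipeline tests (coarse grid, real presets'
# statistical structure scaled down).
small_cohort <- function(group = "AC", n = 5L, seed = 1L,
                         keep_masks = FALSE) {
  generate_cohort(
    phantom_preset(group, grid_shape = c(96L, 96L, 96L), spacing = c(2, 2, 2)),
    n, group, seed, keep_masks = keep_masks)
}

# Deterministic ICV table: two groups, a reference method plus tool-like
# methods with known bias, two phases.
toy_icv_table <- function(seed = 1L, n = 8L, bias = c(fs = 1.08, spm = 0.9),
                          cv = 0.03) {
  set.seed(seed)
  rows <- list()
  for (g in c("AD", "AC")) {
    truth <- rnorm(n, 1.48, 0.15)
    sex <- rep(c("F", "M"), length.out = n)
    age <- round(rnorm(n, 76, 8), 1)
    ids <- sprintf("%s%02d", g, seq_len(n))
    for (ph in 1:2) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = ids, group = g, sex = sex, age = age,
        method = "manual_op1", phase = ph,
        icv_l = truth * (1 + rnorm(n, 0, 1e-4)))
      for (mth in names(bias))
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = ids, group = g, sex = sex, age = age,
          method = mth, phase = ph,
          icv_l = truth * bias[[mth]] * (1 + rnorm(n, 0, cv)))
    }
  }
  icvsampler:::validate_icv_table(do.call(rbind, rows))
}
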