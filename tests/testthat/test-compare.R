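test_that("mrpad matches hand arithmetic and is scale-invariant", {
  expect_identical(mrpad(c(1, 2), c(1, 2)), 0)
  expect_equal(mrpad(c(1.1, 1.8), c(1.0, 2.0)), 10, tolerance = 1e-12)
  ref <- c(0.8, 1.2, 1.9)
  expect_equal(mrpad(2 * ref, ref), 100, tolerance = 1e-12)
  set.seed(5)
  est <- ref * (1 + rnorm(3, 0, 0.1))
  expect_equal(mrpad(est, ref), mrpad(3.7 * est, 3.7 * ref),
               tolerance = 1e-12)
  expect_error(mrpad(1, c(1, 2)), class = "icv_input_error")
  expect_error(mrpad(c(1, 2), c(1, 0)), class = "icv_input_error")
})

test_that("paired t-test matches the hand-worked example and stats::t.test", {
  r <- paired_t_test(c(1, 2, 4), c(2, 3, 4))
  expect_equal(r$t_stat, -2, tolerance = 1e-12)
  expect_identical(r$df, 2L)
  expect_equal(r$p_value, 0.1835, tolerance = 5e-4)

  set.seed(8)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    a <- rnorm(n, 1.5, 0.2)
    b <- a + rnorm(n, 0.02, 0.05)
    mine <- paired_t_test(a, b)
    ref <- t.test(a, b, paired = TRUE)
    expect_equal(mine$t_stat, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter))
    expect_true(mine$p_value >= 0 && mine$p_value <= 1)
  }
})

test_that("paired t-test flags degenerate differences", {
  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$t_stat, 0)
  expect_identical(same$p_value, 1)
  expect_true(same$degenerate)
  shift <- paired_t_test(c(2, 3, 4), c(1, 2, 3))
  expect_true(shift$degenerate)
  expect_identical(shift$t_stat, Inf)
  expect_true(is.na(shift$p_value))
  expect_error(paired_t_test(1, 1), class = "icv_input_error")
})

test_that("a constant shift becomes ever more significant with n", {
  ps <- vapply(c(4, 8, 16, 32, 64), function(n) {
    set.seed(n)
    a <- rnorm(n, 1.5, 0.1)
    paired_t_test(a, a + 0.05 + rnorm(n, 0, 0.02))$p_value
  }, numeric(1))
  expect_true(all(diff(log(ps)) < 0))
})

test_that("pearson_r matches hand-computed covariance arithmetic", {
  expect_identical(pearson_r(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_identical(pearson_r(c(1, 2, 3), -c(1, 2, 3)), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8,
               tolerance = 1e-12)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)),
               class = "icv_degenerate_error")
})

test_that("paired t rejection under the null is calibrated at alpha = 0.05", {
  set.seed(123)
  n_sims <- 2000
  n <- 11
  rej <- 0L
  for (i in 1:n_sims) {
    truth <- rnorm(n, 1.48, 0.15)
    a <- truth * (1 + rnorm(n, 0, 0.005))
    b <- truth * (1 + rnorm(n, 0, 0.005))
    if (paired_t_test(a, b)$p_value < 0.05) rej <- rej + 1L
  }
  band <- qbinom(c(0.005, 0.995), n_sims, 0.05)
  expect_gte(rej, band[1])
  expect_lte(rej, band[2])
})

test_that("single two-level factor ANOVA F equals the squared t statistic", {
  set.seed(9)
  tab <- data.frame(group = rep(c("AD", "AC"), each = 10),
                    icv_l = c(rnorm(10, 1.5, 0.1), rnorm(10, 1.42, 0.1)))
  an <- factorial_glm_anova(tab, icv_l ~ group)
  tt <- t.test(icv_l ~ group, data = tab, var.equal = TRUE)
  expect_equal(an$f_value, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(an$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("a null factor in a balanced noise-free 2x2 design carries zero sum of squares", {
  cells <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"),
                       rep = 1:3, KEEP.OUT.ATTRS = FALSE)
  # means depend on A only; B is null; no noise
  cells$icv_l <- ifelse(cells$A == "a1", 1.4, 1.6)
  expect_warning(an <- factorial_glm_anova(cells, icv_l ~ A * B),
                 "zero residual variance")
  expect_identical(an$f_value[an$term == "B"], 0)
  expect_identical(an$f_value[an$term == "A:B"], 0)
  expect_identical(an$f_value[an$term == "A"], Inf)
  expect_lt(abs(an$sum_sq[an$term == "B"]), 1e-12)
})

test_that("Type III F matches an explicit design-matrix OLS oracle", {
  set.seed(14)
  for (i in 1:10) {
    tab <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2", "b3"),
                       rep = 1:4, KEEP.OUT.ATTRS = FALSE)
    tab$icv_l <- 1.5 + 0.1 * (tab$A == "a2") - 0.05 * (tab$B == "b2") +
      rnorm(nrow(tab), 0, 0.08)
    an <- factorial_glm_anova(tab, icv_l ~ A * B)

    # oracle: full design matrix with sum contrasts; per term, compare RSS
    # of the full fit against the fit with that term's columns removed
    mf <- model.matrix(~ A * B, tab,
                       contrasts.arg = list(A = "contr.sum",
                                            B = "contr.sum"))
    y <- tab$icv_l
    rss <- function(X) sum(qr.resid(qr(X), y)^2)
    rss_full <- rss(mf)
    df_res <- nrow(tab) - ncol(mf)
    asg <- attr(mf, "assign")
    labs <- attr(terms(~ A * B), "term.labels")
    for (t_i in seq_along(labs)) {
      X0 <- mf[, asg != t_i, drop = FALSE]
      df_t <- sum(asg == t_i)
      f_oracle <- ((rss(X0) - rss_full) / df_t) / (rss_full / df_res)
      expect_equal(an$f_value[an$term == labs[t_i]], f_oracle,
                   tolerance = 1e-8)
    }
  }
})

test_that("factorial_glm_anova rejects rank-deficient designs naming the alias", {
  tab <- data.frame(A = rep(c("a1", "a2"), each = 4),
                    B = rep(c("b1", "b2"), each = 4),  # aliased with A
                    icv_l = rnorm(8, 1.5, 0.1))
  expect_error(factorial_glm_anova(tab, icv_l ~ A + B),
               class = "icv_rank_error")
  expect_error(factorial_glm_anova(tab[tab$A == "a1", ], icv_l ~ A),
               class = "icv_input_error")
})

test_that("comparison battery recovers identity, bias and noise structure", {
  tab <- toy_icv_table()
  # a method identical to the reference
  self <- tab[tab$method == "manual_op1" & tab$phase == 1, ]
  dup <- self; dup$method <- "copy"
  both <- icvsampler:::validate_icv_table(rbind(tab, dup))
  res <- comparison_battery(both, "manual_op1", group = "AD",
                            methods = "copy")
  expect_identical(res$t_stat, 0)
  expect_equal(res$pearson_r, 1, tolerance = 1e-12)
  expect_identical(res$mrpad_percent, 0)

  # deterministic 2.77x bias at n = 11: MRPAD 177, strongly significant
  set.seed(31)
  truth <- rnorm(11, 1.48, 0.15)
  tab2 <- icv_table(
    subject_id = rep(sprintf("S%02d", 1:11), 2),
    group = "AD", sex = "F", age = 75,
    method = rep(c("manual_op1", "fsl"), each = 11), phase = 1L,
    icv_l = c(truth, simulate_tool_icv(truth, tool_model("fsl", 2.77), 5)))
  res2 <- comparison_battery(tab2, "manual_op1", group = "AD")
  expect_equal(res2$mrpad_percent, 177, tolerance = 1e-10)
  expect_lt(res2$p_value, 0.01)

  # two phases of a noisy tool: intra-method MRPAD > 0, r < 1
  cons <- phase_consistency_battery(tab, group = "AC", methods = "fs")
  expect_gt(cons$mrpad_percent, 0)
  expect_lt(cons$pearson_r, 1)

  # missing pair detection
  broken <- tab[!(tab$subject_id == "AD01" & tab$method == "fs"), ]
  expect_error(
    comparison_battery(icvsampler:::validate_icv_table(broken),
                       "manual_op1", group = "AD"),
    class = "icv_pairing_error")
})
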