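#' Intraclass correlation from a two-way random-effects ANOVA
#'
#' Single-measure intraclass correlation coefficient for two paired
#' measurement series (k = 2 "raters" rating n targets), computed from the
#' two-way random-effects ANOVA decomposition. The default, absolute
#' agreement (Shrout-Fleiss ICC(2,1)), penalises systematic differences
#' between the series:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + k (MS_C - MS_E)/n}}
#' with \eqn{MS_R} the between-target, \eqn{MS_C} the between-rater and
#' \eqn{MS_E} the residual mean square. The consistency variant
#' \eqn{(MS_R - MS_E)/(MS_R + (k-1) MS_E)} ignores rater offsets.
#'
#' The residual mean square is computed directly from centred paired
#' differences (for k = 2, \eqn{MS_E = \sum_i (d_i - \bar d)^2 / (2(n-1))}
#' with \eqn{d_i = x_i - y_i}), which keeps it non-negative and guarantees
#' ICC <= 1 in floating point.
#'
#' @param x,y paired numeric vectors of equal length n >= 2.
#' @param type `"agreement"` (default, ICC(2,1) absolute agreement) or
#'   `"consistency"`.
#' @return the ICC, a scalar <= 1. Equals 1 exactly when `y == x`
#'   elementwise (with non-zero between-target variance).
#' @examples
#' icc_two_way_random(c(1, 2, 3), c(2, 3, 4))  # 2/3
#' @export
icc_two_way_random <- function(x, y, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  check_numeric_vector(x, "x")
  check_numeric_vector(y, "y")
  n <- length(x)
  if (length(y) != n)
    stop_icv("`x` and `y` must have equal length", "icv_input_error")
  if (n < 2L)
    stop_icv("ICC requires at least 2 paired observations", "icv_input_error")
  ms <- icc_mean_squares(x, y)
  if (ms$msr == 0 && ms$msc == 0 && ms$mse == 0)
    stop_icv("all values identical: ICC is undefined (zero total variance)",
             "icv_degenerate_error")
  icc_from_ms(ms$msr, ms$msc, ms$mse, n, type)
}

# Two-way mean squares for k = 2 raters.
icc_mean_squares <- function(x, y) {
  n <- length(x)
  rowm <- (x + y) / 2
  grand <- mean(rowm)
  msr <- 2 * sum((rowm - grand)^2) / (n - 1)
  # For k = 2, MSC and MSE reduce to functions of the paired differences;
  # computing them that way keeps both non-negative (so ICC <= 1 holds in
  # floating point) and exactly zero in the perfect-agreement case.
  d <- x - y
  msc <- n * mean(d)^2 / 2
  mse <- sum((d - mean(d))^2) / (2 * (n - 1))
  list(msr = msr, msc = msc, mse = mse)
}

icc_from_ms <- function(msr, msc, mse, n, type) {
  if (type == "agreement")
    (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
  else
    (msr - mse) / (msr + mse)
}

# Vectorised ICC of one reference vector against every row of an estimate
# matrix (reps x n). Same decomposition as icc_two_way_random(); used by
# the randomized reliability analysis where thousands of ICCs are needed.
icc_many <- function(ref, est, type = "agreement") {
  n <- length(ref)
  est <- matrix(est, ncol = n)
  mx <- mean(ref)
  my <- rowMeans(est)
  cr <- ref - mx
  ce <- est - my  # my (length = nrow) recycles down columns: row-centring
  # MSR_i = sum_j (cr_j + ce_ij)^2 / (2 (n - 1))
  msr <- (sum(cr^2) + 2 * as.vector(ce %*% cr) + rowSums(ce^2)) /
    (2 * (n - 1))
  d <- matrix(ref, nrow(est), n, byrow = TRUE) - est
  dbar <- rowMeans(d)
  msc <- n * dbar^2 / 2
  dc <- d - dbar
  mse <- rowSums(dc^2) / (2 * (n - 1))
  if (type == "agreement")
    (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
  else
    (msr - mse) / (msr + mse)
}
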