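#' Mean related percentage of absolute difference (MRPAD)
#'
#' The agreement statistic used to score automated tools and repeated
#' tracings against a reference measurement:
#' \deqn{MRPAD = \frac{1}{n} \sum_{i=1}^n \frac{|est_i - ref_i|}{ref_i}
#'   \times 100.}
#' It is invariant under rescaling both series by the same positive factor.
#'
#' @param estimates,references paired numeric vectors of equal length
#'   n >= 1; references strictly positive.
#' @return MRPAD in percent (>= 0).
#' @examples
#' mrpad(c(1.1, 1.8), c(1.0, 2.0))  # 10
#' @export
mrpad <- function(estimates, references) {
  check_numeric_vector(estimates, "estimates")
  check_numeric_vector(references, "references", positive = TRUE)
  if (length(estimates) != length(references) || length(estimates) < 1L)
    stop_icv("`estimates` and `references` must be equal-length, length >= 1",
             "icv_input_error")
  mean(abs(estimates - references) / references) * 100
}

#' Two-sided paired t-test
#'
#' Paired t statistic and two-sided p-value from the t distribution with
#' n - 1 degrees of freedom. When the paired differences have zero
#' variance the result is flagged degenerate: `t = 0, p = 1` if the series
#' are identical, otherwise `t = +/-Inf` with `p = NA`.
#'
#' @param a,b paired numeric vectors of equal length n >= 2.
#' @return list with `t_stat`, `p_value`, `df`, `mean_diff`, `n`,
#'   `degenerate`.
#' @examples
#' paired_t_test(c(1, 2, 4), c(2, 3, 4))  # t = -2, df = 2, p ~ 0.1835
#' @export
paired_t_test <- function(a, b) {
  check_numeric_vector(a, "a")
  check_numeric_vector(b, "b")
  n <- length(a)
  if (length(b) != n || n < 2L)
    stop_icv("`a` and `b` must be equal-length with n >= 2", "icv_input_error")
  d <- a - b
  md <- mean(d)
  s <- sd(d)
  df <- n - 1L
  if (s == 0) {
    if (md == 0)
      return(list(t_stat = 0, p_value = 1, df = df, mean_diff = 0, n = n,
                  degenerate = TRUE))
    return(list(t_stat = sign(md) * Inf, p_value = NA_real_, df = df,
                mean_diff = md, n = n, degenerate = TRUE))
  }
  t_stat <- md / (s / sqrt(n))
  list(t_stat = t_stat, p_value = 2 * pt(-abs(t_stat), df), df = df,
       mean_diff = md, n = n, degenerate = FALSE)
}

#' Pearson product-moment correlation
#'
#' Standard Pearson correlation, clamped to [-1, 1] against rounding.
#' Errors if either series has zero variance.
#'
#' @param a,b numeric vectors of equal length n >= 2 with non-zero
#'   variance.
#' @return correlation in [-1, 1].
#' @export
pearson_r <- function(a, b) {
  check_numeric_vector(a, "a")
  check_numeric_vector(b, "b")
  if (length(a) != length(b) || length(a) < 2L)
    stop_icv("`a` and `b` must be equal-length with n >= 2", "icv_input_error")
  if (sd(a) == 0 || sd(b) == 0)
    stop_icv("correlation undefined: a series has zero variance",
             "icv_degenerate_error")
  min(1, max(-1, cor(a, b)))
}

#' ICV measurement table
#'
#' Long-format container for the study's measurements: one row per
#' (subject, method, phase). Validates positivity of the volumes and
#' uniqueness of (subject_id, method, phase).
#'
#' @param subject_id,group,sex,method character vectors (recycled scalars
#'   allowed); `group` in {AD, AC}, `sex` in {F, M}.
#' @param age numeric, years.
#' @param phase integer measurement phase (1 or 2).
#' @param icv_l volumes in litres (> 0).
#' @return a data frame of class `icv_table` with exactly those columns.
#' @export
icv_table <- function(subject_id, group, sex, age, method, phase, icv_l) {
  tab <- data.frame(subject_id = as.character(subject_id),
                    group = as.character(group), sex = as.character(sex),
                    age = as.double(age), method = as.character(method),
                    phase = as.integer(phase), icv_l = as.double(icv_l),
                    stringsAsFactors = FALSE)
  validate_icv_table(tab)
}

validate_icv_table <- function(tab) {
  required <- c("subject_id", "group", "sex", "age", "method", "phase",
                "icv_l")
  if (!all(required %in% names(tab)))
    stop_icv(paste("icv_table needs columns:",
                   paste(required, collapse = ", ")), "icv_input_error")
  if (any(!is.finite(tab$icv_l)) || any(tab$icv_l <= 0))
    stop_icv("all `icv_l` values must be positive and finite",
             "icv_input_error")
  key <- paste(tab$subject_id, tab$method, tab$phase)
  if (anyDuplicated(key))
    stop_icv("(subject_id, method, phase) must be unique", "icv_input_error")
  class(tab) <- c("icv_table", "data.frame")
  tab
}

#' Read / write an ICV measurement table as CSV
#'
#' @param path CSV file with the [icv_table()] columns.
#' @return `read_icv_table()` returns a validated `icv_table`;
#'   `write_icv_table()` returns `path` invisibly.
#' @export
read_icv_table <- function(path) {
  validate_icv_table(read.csv(path, stringsAsFactors = FALSE))
}

#' @param tab an [icv_table()].
#' @rdname read_icv_table
#' @export
write_icv_table <- function(tab, path) {
  write.csv(validate_icv_table(tab), path, row.names = FALSE)
  invisible(path)
}

#' Factorial GLM analysis of measured ICV
#'
#' Least-squares fit of ICV on the study factors (by default group, sex,
#' age and estimation method with all interactions up to the four-way
#' term), with per-term F statistics and p-values from Type III sums of
#' squares under sum-to-zero contrasts. Method enters as an ordinary
#' between-style factor; the F test for method therefore ignores the
#' within-subject correlation of repeated measurements (see the package
#' vignette).
#'
#' @param table a data frame containing the model variables (e.g. an
#'   [icv_table()]).
#' @param formula model formula; default
#'   `icv_l ~ group * sex * age * method`. Character variables are
#'   converted to factors; every factor must have at least 2 levels in the
#'   data. Numeric covariates are mean-centred so that, under the
#'   sum-to-zero contrasts, each Type III main effect is evaluated at the
#'   covariate mean rather than extrapolated to zero.
#' @return a data frame of class `anova_table` with columns `term`, `df`,
#'   `sum_sq`, `f_value`, `p_value` (main effects first, then
#'   interactions), plus a `residual` attribute with the residual df and
#'   mean square.
#' @export
factorial_glm_anova <- function(table,
                                formula = icv_l ~ group * sex * age * method) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop_icv("`table` must be a non-empty data frame", "icv_input_error")
  vars <- all.vars(formula)
  missing_vars <- setdiff(vars, names(table))
  if (length(missing_vars))
    stop_icv(paste("missing model variables:",
                   paste(missing_vars, collapse = ", ")), "icv_input_error")
  dat <- as.data.frame(table)[vars]
  contr <- list()
  for (v in setdiff(vars, all.vars(formula[[2L]]))) {
    if (is.character(dat[[v]]) || is.logical(dat[[v]]))
      dat[[v]] <- factor(dat[[v]])
    if (is.factor(dat[[v]])) {
      dat[[v]] <- droplevels(dat[[v]])
      if (nlevels(dat[[v]]) < 2L)
        stop_icv(sprintf("factor `%s` has fewer than 2 levels", v),
                 "icv_input_error")
      contr[[v]] <- "contr.sum"
    } else if (is.numeric(dat[[v]])) {
      dat[[v]] <- dat[[v]] - mean(dat[[v]])
    }
  }
  fit <- lm(formula, data = dat,
            contrasts = if (length(contr)) contr else NULL)
  cf <- coef(fit)
  if (anyNA(cf))
    stop_icv(paste("rank-deficient design; aliased coefficients:",
                   paste(names(cf)[is.na(cf)], collapse = ", ")),
             "icv_rank_error")
  y <- dat[[all.vars(formula[[2L]])[1L]]]
  mm <- stats::model.matrix(fit)
  rss_full <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  if (rss_full > 1e-10 * max(tss, 1e-300)) {
    an <- car::Anova(fit, type = 3)
    keep <- !(rownames(an) %in% c("(Intercept)", "Residuals"))
    out <- data.frame(term = rownames(an)[keep],
                      df = an$Df[keep],
                      sum_sq = an$`Sum Sq`[keep],
                      f_value = an$`F value`[keep],
                      p_value = an$`Pr(>F)`[keep],
                      stringsAsFactors = FALSE)
    resid_row <- which(rownames(an) == "Residuals")
    attr(out, "residual") <- list(df = an$Df[resid_row],
                                  mean_sq = an$`Sum Sq`[resid_row] /
                                    an$Df[resid_row])
  } else {
    # Degenerate noise-free fit: car::Anova refuses a zero residual sum of
    # squares. Compute the Type III sums of squares directly (drop each
    # term's columns from the sum-contrast design; equivalent under these
    # contrasts) and report limit-case F: 0 for terms with no sum of
    # squares, Inf otherwise.
    warning("zero residual variance: F statistics are limit values")
    asg <- attr(mm, "assign")
    labs <- attr(stats::terms(fit), "term.labels")
    ss <- df_t <- numeric(length(labs))
    for (t_i in seq_along(labs)) {
      X0 <- mm[, asg != t_i, drop = FALSE]
      ss[t_i] <- sum(stats::lsfit(X0, y, intercept = FALSE)$residuals^2) -
        rss_full
      df_t[t_i] <- sum(asg == t_i)
    }
    null_term <- ss <= 1e-10 * max(tss, 1e-300)
    out <- data.frame(term = labs, df = as.integer(df_t), sum_sq = ss,
                      f_value = ifelse(null_term, 0, Inf),
                      p_value = ifelse(null_term, 1, 0),
                      stringsAsFactors = FALSE)
    attr(out, "residual") <- list(df = nrow(mm) - ncol(mm), mean_sq = 0)
  }
  rownames(out) <- NULL
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Method agreement battery against a reference
#'
#' For each non-reference method present in the chosen group and phase,
#' compares its measurements with the reference method subject by subject:
#' paired t-test, Pearson correlation and [mrpad()] (the Table-4-style
#' summary). Errors if any subject lacks a reference or method
#' measurement.
#'
#' @param table an [icv_table()].
#' @param reference_method method label of the reference (default
#'   `"manual_op1"`).
#' @param group optional group filter (`"AD"`, `"AC"`); `NULL` uses all
#'   rows.
#' @param phase measurement phase to compare within (default 1).
#' @param methods methods to compare; default all non-reference methods in
#'   the selection.
#' @return a data frame of class `comparison_result`: one row per method
#'   with `group`, `method_a` (reference), `method_b`, `n`, `t_stat`,
#'   `p_value`, `df`, `pearson_r`, `mrpad_percent`.
#' @export
comparison_battery <- function(table, reference_method = "manual_op1",
                               group = NULL, phase = 1L, methods = NULL) {
  tab <- validate_icv_table(table)
  if (!is.null(group)) tab <- tab[tab$group %in% group, , drop = FALSE]
  tab <- tab[tab$phase == phase, , drop = FALSE]
  ref <- tab[tab$method == reference_method, , drop = FALSE]
  if (nrow(ref) == 0L)
    stop_icv(sprintf("reference method '%s' absent from the selection",
                     reference_method), "icv_input_error")
  if (is.null(methods))
    methods <- setdiff(unique(tab$method), reference_method)
  rows <- lapply(methods, function(mth) {
    est <- tab[tab$method == mth, , drop = FALSE]
    pair_comparison_row(ref, est, label_a = reference_method, label_b = mth,
                        group = if (is.null(group)) "all" else
                          paste(group, collapse = "+"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("comparison_result", "data.frame")
  out
}

#' Phase consistency battery
#'
#' Compares each method's phase-1 and phase-2 measurements subject by
#' subject (paired t-test, Pearson correlation, [mrpad()] with phase 1 as
#' reference) — the intra-operator / intra-software consistency analysis
#' (Table-5-style summary).
#'
#' @inheritParams comparison_battery
#' @param methods methods to check; default all methods present in both
#'   phases.
#' @return a `comparison_result` data frame, one row per method, with
#'   `method_a = <method>@phase1` and `method_b = <method>@phase2`.
#' @export
phase_consistency_battery <- function(table, group = NULL, methods = NULL) {
  tab <- validate_icv_table(table)
  if (!is.null(group)) tab <- tab[tab$group %in% group, , drop = FALSE]
  p1 <- tab[tab$phase == 1L, , drop = FALSE]
  p2 <- tab[tab$phase == 2L, , drop = FALSE]
  if (is.null(methods))
    methods <- intersect(unique(p1$method), unique(p2$method))
  if (!length(methods))
    stop_icv("no method present in both phases", "icv_input_error")
  rows <- lapply(methods, function(mth) {
    pair_comparison_row(p1[p1$method == mth, , drop = FALSE],
                        p2[p2$method == mth, , drop = FALSE],
                        label_a = paste0(mth, "@phase1"),
                        label_b = paste0(mth, "@phase2"),
                        group = if (is.null(group)) "all" else
                          paste(group, collapse = "+"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("comparison_result", "data.frame")
  out
}

# Align two measurement sets on subject_id and compute the agreement row.
# `a` is the reference for MRPAD.
pair_comparison_row <- function(a, b, label_a, label_b, group) {
  missing_b <- setdiff(a$subject_id, b$subject_id)
  missing_a <- setdiff(b$subject_id, a$subject_id)
  if (length(missing_a) || length(missing_b))
    stop_icv(sprintf(
      "unpaired subjects for %s vs %s: %s", label_a, label_b,
      paste(union(missing_a, missing_b), collapse = ", ")),
      "icv_pairing_error")
  b <- b[match(a$subject_id, b$subject_id), , drop = FALSE]
  tt <- paired_t_test(b$icv_l, a$icv_l)
  r <- if (sd(a$icv_l) > 0 && sd(b$icv_l) > 0)
    pearson_r(a$icv_l, b$icv_l) else NA_real_
  data.frame(group = group, method_a = label_a, method_b = label_b,
             n = nrow(a), t_stat = tt$t_stat, p_value = tt$p_value,
             df = tt$df, pearson_r = r,
             mrpad_percent = mrpad(b$icv_l, a$icv_l),
             stringsAsFactors = FALSE)
}
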