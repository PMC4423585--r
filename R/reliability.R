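#' Maximum percentage error
#'
#' Largest per-subject percentage deviation of the estimates from the
#' references: `max(|est - ref| / ref) * 100`.
#'
#' @param estimates,references paired numeric vectors of equal length;
#'   references strictly positive.
#' @return MPE in percent (>= 0).
#' @export
max_percentage_error <- function(estimates, references) {
  check_numeric_vector(estimates, "estimates")
  check_numeric_vector(references, "references", positive = TRUE)
  if (length(estimates) != length(references) || length(estimates) < 1L)
    stop_icv("`estimates` and `references` must be equal-length, length >= 1",
             "icv_input_error")
  max(abs(estimates - references) / references) * 100
}

# Normalise the cohort argument of the reliability runner into per-subject
# slice profiles: list(counts, first, last, spacing).
cohort_profiles <- function(cohort) {
  as_profile <- function(x) {
    if (is_mask_volume(x))
      list(counts = slice_counts(x), spacing = x$spacing)
    else if (inherits(x, "slice_profile")) unclass(x)
    else NULL
  }
  if (inherits(cohort, "icv_cohort")) {
    counts <- cohort$profiles
    spacing <- rep(list(cohort$spacing), length(counts))
  } else if (is.list(cohort) &&
             !any(vapply(cohort, function(x) is.null(as_profile(x)),
                         logical(1)))) {
    prof <- lapply(cohort, as_profile)
    counts <- lapply(prof, `[[`, "counts")
    spacing <- lapply(prof, `[[`, "spacing")
  } else {
    stop_icv("`cohort` must be an icv_cohort or a list of mask_volume",
             "icv_input_error")
  }
  lapply(seq_along(counts), function(i) {
    occ <- which(counts[[i]] > 0)
    if (!length(occ))
      stop_icv(sprintf("subject %d has an empty mask", i),
               "icv_empty_mask_error")
    list(counts = counts[[i]], first = occ[1L], last = occ[length(occ)],
         spacing = spacing[[i]])
  })
}

#' Randomized reliability analysis of the subsampling protocol
#'
#' For every sampling period `m` and repetition, a start offset is drawn
#' uniformly from `0 .. m-1` (independently per subject by default), every
#' subject's ICV is re-estimated by [subsample_icv()] with that offset, and
#' two statistics are recorded against the reference ICVs: the two-way
#' random-effects absolute-agreement ICC ([icc_two_way_random()]) and the
#' maximum percentage error over subjects ([max_percentage_error()]).
#' Repeating this (default 5000 times) yields an empirical ICC distribution
#' per sampling period.
#'
#' @param cohort an `icv_cohort` (see [generate_cohort()]) or a list of
#'   [mask_volume()] objects; at least 2 subjects.
#' @param reference_icvs reference volumes in litres; defaults to each
#'   subject's full voxel-count ICV.
#' @param periods integer sampling periods to evaluate (typically `2:40`;
#'   `m = 1` is accepted and reproduces the reference exactly).
#' @param n_reps repetitions per period (default 5000).
#' @param seed integer seed; the draw list is deterministic given it.
#' @param shared_starts if `TRUE`, one start offset per repetition is
#'   shared by all subjects instead of independent per-subject draws.
#' @param icc_type ICC variant, `"agreement"` (default) or `"consistency"`.
#' @return a data frame of class `icc_draws` with columns `m`, `rep`,
#'   `icc`, `mpe_percent`.
#' @export
run_randomized_reliability <- function(cohort, reference_icvs = NULL,
                                       periods = 2:40, n_reps = 5000L,
                                       seed = 1L, shared_starts = FALSE,
                                       icc_type = "agreement") {
  profiles <- cohort_profiles(cohort)
  n_subj <- length(profiles)
  if (n_subj < 2L)
    stop_icv("reliability analysis needs at least 2 subjects",
             "icv_input_error")
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1L)
    stop_icv("`n_reps` must be >= 1", "icv_input_error")
  periods <- sort(unique(as.integer(periods)))
  if (any(is.na(periods)) || any(periods < 1L))
    stop_icv("`periods` must be integers >= 1", "icv_input_error")
  if (is.null(reference_icvs))
    reference_icvs <- vapply(profiles, function(p)
      voxel_count_to_litres(as.double(sum(p$counts)), p$spacing), numeric(1))
  check_numeric_vector(reference_icvs, "reference_icvs", positive = TRUE)
  if (length(reference_icvs) != n_subj)
    stop_icv("`reference_icvs` must match the cohort size", "icv_input_error")

  out <- vector("list", length(periods))
  with_seed(seed, {
    for (pi in seq_along(periods)) {
      m <- periods[pi]
      # all m start-offset sums per subject, computed once
      sums <- lapply(profiles, function(p) {
        ct <- p$counts[p$first:p$last]
        s <- numeric(m)
        grp <- (seq_along(ct) - 1L) %% m
        agg <- rowsum(as.double(ct), grp)
        s[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
        s
      })
      starts <- if (shared_starts) {
        matrix(rep(sample.int(m, n_reps, replace = TRUE) - 1L, n_subj),
               nrow = n_reps)
      } else {
        matrix(sample.int(m, n_reps * n_subj, replace = TRUE) - 1L,
               nrow = n_reps)
      }
      est <- matrix(0, n_reps, n_subj)
      for (j in seq_len(n_subj))
        est[, j] <- voxel_count_to_litres(m * sums[[j]][starts[, j] + 1L],
                                          profiles[[j]]$spacing)
      icc <- icc_many(reference_icvs, est, type = icc_type)
      relerr <- abs(est - matrix(reference_icvs, n_reps, n_subj,
                                 byrow = TRUE)) /
        matrix(reference_icvs, n_reps, n_subj, byrow = TRUE)
      mpe <- do.call(pmax, as.data.frame(relerr)) * 100
      out[[pi]] <- data.frame(m = m, rep = seq_len(n_reps), icc = icc,
                              mpe_percent = mpe)
    }
  })
  draws <- do.call(rbind, out)
  rownames(draws) <- NULL
  class(draws) <- c("icc_draws", "data.frame")
  draws
}

#' Summarise ICC draws into a reliability curve
#'
#' Per sampling period: the 5th, 25th, 50th, 75th and 95th percentiles of
#' the empirical ICC distribution, the spread (95th minus 5th percentile),
#' and summaries of the per-repetition maximum percentage error (min, max
#' and the [p5, p95] band read as a 90% confidence interval). Percentiles
#' use linear interpolation between order statistics
#' (`stats::quantile(type = 7)`).
#'
#' @param draws an `icc_draws` data frame from
#'   [run_randomized_reliability()].
#' @return a data frame of class `reliability_curve` with one row per
#'   period: `m`, `icc_p5` .. `icc_p95`, `icc_spread`, `mpe_min`, `mpe_p5`,
#'   `mpe_p95`, `mpe_max`, `n_reps`.
#' @export
summarize_curve <- function(draws) {
  if (!is.data.frame(draws) || nrow(draws) == 0L ||
      !all(c("m", "icc", "mpe_percent") %in% names(draws)))
    stop_icv("`draws` must be a non-empty icc_draws data frame",
             "icv_input_error")
  rows <- lapply(split(draws, draws$m), function(d) {
    q <- quantile(d$icc, c(0.05, 0.25, 0.50, 0.75, 0.95),
                  names = FALSE, type = 7)
    mq <- quantile(d$mpe_percent, c(0.05, 0.95), names = FALSE, type = 7)
    data.frame(m = d$m[1L],
               icc_p5 = q[1], icc_p25 = q[2], icc_p50 = q[3],
               icc_p75 = q[4], icc_p95 = q[5],
               icc_spread = q[5] - q[1],
               mpe_min = min(d$mpe_percent), mpe_p5 = mq[1],
               mpe_p95 = mq[2], mpe_max = max(d$mpe_percent),
               n_reps = nrow(d))
  })
  curve <- do.call(rbind, rows)
  curve <- curve[order(curve$m), , drop = FALSE]
  rownames(curve) <- NULL
  class(curve) <- c("reliability_curve", "data.frame")
  curve
}

#' Maximum safe sampling period from a reliability curve
#'
#' Extracts the protocol guideline: the largest sampling period such that
#' every tested period up to it satisfies the chosen criterion
#' (contiguous-from-smallest rule; isolated passes at large periods are not
#' treated as safe, since the ICC behaves erratically there).
#'
#' Criteria:
#' * `confidence_icc`: the 5th percentile of the ICC distribution is at or
#'   above `icc_threshold`, i.e. at least 95% of random sampling starts
#'   keep the ICC above the threshold;
#' * `tight_spread`: the spread (95th minus 5th ICC percentile) is at most
#'   `spread_max`.
#'
#' @param curve a `reliability_curve` from [summarize_curve()].
#' @param criterion `"confidence_icc"` or `"tight_spread"`.
#' @param icc_threshold reliability threshold (default 0.99).
#' @param confidence probability with which the threshold must be met;
#'   only 0.95 is supported, matching the stored 5th percentile.
#' @param spread_max maximum admissible spread (default 0.005).
#' @param slice_spacing slice spacing in mm, used to express the guideline
#'   in millimetres.
#' @return an object of class `guideline_result`: list with `criterion`,
#'   `satisfied` (FALSE when no tested period passes), `max_period_slices`
#'   (NA when none satisfied), `max_period_mm`, thresholds and `n_reps`.
#' @export
guideline_max_period <- function(curve,
                                 criterion = c("confidence_icc",
                                               "tight_spread"),
                                 icc_threshold = 0.99, confidence = 0.95,
                                 spread_max = 0.005, slice_spacing = 1) {
  criterion <- match.arg(criterion)
  if (!inherits(curve, "data.frame") || nrow(curve) == 0L)
    stop_icv("`curve` must be a non-empty reliability_curve",
             "icv_input_error")
  if (icc_threshold <= 0 || icc_threshold > 1)
    stop_icv("`icc_threshold` must be in (0, 1]", "icv_input_error")
  if (!isTRUE(all.equal(confidence, 0.95)))
    stop_icv("only confidence = 0.95 is supported (the curve stores the 5th percentile)",
             "icv_input_error")
  if (spread_max < 0) stop_icv("`spread_max` must be >= 0", "icv_input_error")
  check_numeric_vector(slice_spacing, "slice_spacing", positive = TRUE)
  curve <- curve[order(curve$m), , drop = FALSE]
  ok <- if (criterion == "confidence_icc") curve$icc_p5 >= icc_threshold
        else curve$icc_spread <= spread_max
  pass <- cumprod(as.integer(ok)) == 1L
  res <- list(criterion = criterion,
              satisfied = any(pass),
              max_period_slices = if (any(pass)) max(curve$m[pass]) else NA_integer_,
              max_period_mm = if (any(pass))
                period_mm(max(curve$m[pass]), slice_spacing) else NA_real_,
              icc_threshold = icc_threshold, confidence = confidence,
              spread_max = spread_max,
              n_reps = if ("n_reps" %in% names(curve)) curve$n_reps[1L] else NA)
  class(res) <- "guideline_result"
  res
}

#' @export
print.guideline_result <- function(x, ...) {
  if (x$satisfied)
    cat(sprintf("<guideline_result> %s: max safe period %d slices (%.3g mm)\n",
                x$criterion, x$max_period_slices, x$max_period_mm))
  else
    cat(sprintf("<guideline_result> %s: no tested period satisfied\n",
                x$criterion))
  invisible(x)
}
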