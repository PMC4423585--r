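# Volume of `count` voxels in litres. One canonical evaluation order is used
# everywhere so that identity cases (m = 1, full sampling) are bit-equal.
voxel_count_to_litres <- function(count, spacing) {
  count * spacing[1] * spacing[2] * spacing[3] / 1e6
}

# Occupied-voxel counts per slice along `axis`.
slice_counts <- function(mask, axis = mask$slice_axis) {
  occ <- mask$occupancy
  switch(axis,
         rowSums(occ, dims = 1L),
         colSums(aperm(occ, c(1L, 3L, 2L)), dims = 2L),
         colSums(occ, dims = 2L))
}

#' Reference ICV by voxel counting
#'
#' The reference ("every slice") ICV: the number of occupied voxels times
#' the voxel volume, in litres (1 L = 1e6 mm^3).
#'
#' @param mask a [mask_volume()].
#' @return volume in litres (0 for an empty mask).
#' @examples
#' m <- mask_volume(array(1L, c(10, 10, 10)), spacing = c(1, 1, 1))
#' icv_from_mask(m)  # 1000 mm^3 = 0.001 L
#' @export
icv_from_mask <- function(mask) {
  if (!is_mask_volume(mask)) stop_icv("`mask` must be a mask_volume",
                                      "icv_input_error")
  voxel_count_to_litres(as.double(sum(mask$occupancy)), mask$spacing)
}

#' Per-slice cavity areas
#'
#' Cross-sectional cavity area of every slice along an axis: occupied voxel
#' count in the slice times the in-plane voxel area. Summing the areas times
#' the slice spacing recovers [icv_from_mask()].
#'
#' @param mask a [mask_volume()].
#' @param slice_axis axis along which to slice (defaults to the mask's).
#' @return numeric vector of areas in mm^2, one entry per slice index.
#' @export
slice_areas <- function(mask, slice_axis = mask$slice_axis) {
  if (!is_mask_volume(mask)) stop_icv("`mask` must be a mask_volume",
                                      "icv_input_error")
  axis <- parse_slice_axis(slice_axis)
  inplane <- prod(mask$spacing[-axis])
  slice_counts(mask, axis) * inplane
}

#' Interleaved slice-subsampling ICV estimate
#'
#' The Cavalieri-type estimator used by sampled manual tracing protocols:
#' starting `start_offset` slices after the first occupied slice, every
#' m-th slice is "traced" and the ICV estimate is m times the summed
#' sampled slice volumes. With `m = 1` and `start_offset = 0` the estimate
#' equals [icv_from_mask()] exactly.
#'
#' @param mask a non-empty [mask_volume()].
#' @param m sampling period in slices (integer >= 1).
#' @param start_offset start offset in slices relative to the first
#'   occupied slice; integer in `[0, m - 1]`.
#' @param slice_axis axis along which slices are taken (defaults to the
#'   mask's slice axis).
#' @return an object of class `subsample_estimate`: list with
#'   `period_slices`, `period_mm`, `start_offset`, `icv_l` and
#'   `n_sampled_slices`.
#' @examples
#' m <- mask_volume(array(1L, c(5, 5, 12)), spacing = c(1, 1, 1))
#' subsample_icv(m, m = 3, start_offset = 0)
#' @export
subsample_icv <- function(mask, m, start_offset = 0L,
                          slice_axis = mask$slice_axis) {
  if (!is_mask_volume(mask)) stop_icv("`mask` must be a mask_volume",
                                      "icv_input_error")
  axis <- parse_slice_axis(slice_axis)
  m <- as.integer(m)
  start_offset <- as.integer(start_offset)
  if (is.na(m) || m < 1L)
    stop_icv("sampling period `m` must be an integer >= 1", "icv_input_error")
  if (is.na(start_offset) || start_offset < 0L || start_offset >= m)
    stop_icv("`start_offset` must lie in [0, m - 1]", "icv_input_error")
  counts <- slice_counts(mask, axis)
  occ <- which(counts > 0)
  if (length(occ) == 0L)
    stop_icv("mask is empty: subsampling estimate undefined",
             "icv_empty_mask_error")
  est <- subsample_from_counts(counts, occ[1L], occ[length(occ)],
                               m, start_offset, mask$spacing)
  dz <- mask$spacing[axis]
  structure(
    list(period_slices = m, period_mm = period_mm(m, dz),
         start_offset = start_offset, icv_l = est$icv_l,
         n_sampled_slices = est$n_sampled),
    class = "subsample_estimate"
  )
}

# Core estimator on a per-slice count vector; `first`/`last` bound the
# occupied range (1-based). Kept separate so the reliability analysis can
# reuse profiles without re-touching voxel data.
subsample_from_counts <- function(counts, first, last, m, start_offset,
                                  spacing) {
  from <- first + start_offset
  idx <- if (from > last) integer(0) else seq.int(from, last, by = m)
  csum <- as.double(sum(counts[idx]))
  list(icv_l = voxel_count_to_litres(m * csum, spacing),
       n_sampled = length(idx))
}

#' @export
print.subsample_estimate <- function(x, ...) {
  cat(sprintf(
    "<subsample_estimate> m = %d (%.3f mm), start %d: %.6f L over %d slices\n",
    x$period_slices, x$period_mm, x$start_offset, x$icv_l,
    x$n_sampled_slices))
  invisible(x)
}

#' Sampling period in millimetres
#'
#' Converts a sampling period in slices to millimetres so that guidelines
#' are comparable across acquisitions with different slice spacing.
#'
#' @param m sampling period in slices (>= 1).
#' @param slice_spacing slice spacing in mm (> 0).
#' @return `m * slice_spacing`, in mm.
#' @examples
#' period_mm(10, 0.938)  # 9.38 mm
#' @export
period_mm <- function(m, slice_spacing) {
  if (any(m < 1)) stop_icv("`m` must be >= 1", "icv_input_error")
  check_numeric_vector(slice_spacing, "slice_spacing", positive = TRUE)
  m * slice_spacing
}
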