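#' Binary cavity mask with voxel spacing
#'
#' Container for a 3D binary occupancy grid together with the physical voxel
#' spacing, the representation used for traced or ground-truth intracranial
#' cavities. Occupancy values must be exactly 0 or 1.
#'
#' @param occupancy 3D array of 0/1 values (any numeric or logical type;
#'   stored as integer).
#' @param spacing numeric length-3 vector, mm per voxel along each array
#'   dimension; all components strictly positive and finite.
#' @param slice_axis axis along which slices are taken for tracing and
#'   subsampling: integer 1, 2 or 3, or one of the labels `"axis0"`,
#'   `"axis1"`, `"axis2"` (0-based, mapping to array dimensions 1-3).
#' @return an object of class `mask_volume`: a list with elements
#'   `occupancy` (integer 3D array), `spacing` (numeric 3-vector) and
#'   `slice_axis` (integer in 1..3).
#' @examples
#' m <- mask_volume(array(1L, c(10, 10, 10)), spacing = c(1, 1, 1))
#' icv_from_mask(m)  # 0.001 L
#' @export
mask_volume <- function(occupancy, spacing = c(1, 1, 1), slice_axis = 3L) {
  if (!is.array(occupancy) || length(dim(occupancy)) != 3L)
    stop_icv("`occupancy` must be a 3D array", "icv_input_error")
  if (is.logical(occupancy)) occupancy <- occupancy + 0L
  if (is.double(occupancy)) {
    occ_int <- as.integer(round(occupancy))
    if (any(abs(occupancy - occ_int) > 0, na.rm = TRUE))
      stop_icv("occupancy values must be exactly 0 or 1", "icv_input_error")
    occupancy <- array(occ_int, dim(occupancy))
  }
  if (anyNA(occupancy) || any(occupancy != 0L & occupancy != 1L))
    stop_icv("occupancy values must be exactly 0 or 1", "icv_input_error")
  check_numeric_vector(spacing, "spacing", positive = TRUE)
  if (length(spacing) != 3L)
    stop_icv("`spacing` must have length 3", "icv_input_error")
  axis <- parse_slice_axis(slice_axis)
  structure(
    list(occupancy = occupancy, spacing = as.double(spacing),
         slice_axis = axis),
    class = "mask_volume"
  )
}

parse_slice_axis <- function(slice_axis) {
  if (is.character(slice_axis)) {
    lab <- match.arg(slice_axis, c("axis0", "axis1", "axis2"))
    return(match(lab, c("axis0", "axis1", "axis2")))
  }
  axis <- as.integer(slice_axis)
  if (length(axis) != 1L || is.na(axis) || axis < 1L || axis > 3L)
    stop_icv("`slice_axis` must be 1, 2, 3 or an 'axis0'..'axis2' label",
             "icv_input_error")
  axis
}

#' @export
print.mask_volume <- function(x, ...) {
  d <- dim(x$occupancy)
  cat(sprintf(
    "<mask_volume> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  slice axis: %d; occupied voxels: %.0f; volume: %.4f L\n",
              x$slice_axis, sum(x$occupancy), icv_from_mask(x)))
  invisible(x)
}

#' @export
format.mask_volume <- function(x, ...) {
  d <- dim(x$occupancy)
  sprintf("<mask_volume %dx%dx%d>", d[1], d[2], d[3])
}

is_mask_volume <- function(x) inherits(x, "mask_volume")

# slice spacing (mm) along the mask's slice axis
slice_spacing_of <- function(mask, slice_axis = mask$slice_axis) {
  mask$spacing[parse_slice_axis(slice_axis)]
}

#' Write a mask to a NIfTI-1 file
#'
#' Occupancy is stored as unsigned 8-bit with the voxel spacing in the
#' header.
#'
#' @param mask a [mask_volume()].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(mask, path) {
  if (!is_mask_volume(mask)) stop_icv("`mask` must be a mask_volume",
                                      "icv_input_error")
  occ <- mask$occupancy
  attr(occ, "pixdim") <- mask$spacing
  img <- RNifti::asNifti(occ, datatype = "uint8", internal = FALSE)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a mask from a NIfTI-1 file
#'
#' @param path NIfTI file written by [write_mask_nifti()] or any binary
#'   (0/1) NIfTI volume.
#' @param slice_axis slice axis to attach (see [mask_volume()]).
#' @return a [mask_volume()].
#' @export
read_mask_nifti <- function(path, slice_axis = 3L) {
  img <- RNifti::readNifti(path)
  occ <- array(as.integer(img), dim(img))
  mask_volume(occ, spacing = RNifti::pixdim(img)[1:3],
              slice_axis = slice_axis)
}
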