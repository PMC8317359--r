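#' PET SUV volume
#'
#' Container for a 3-D grid of standardized uptake values (SUV, already
#' body-weight normalised) with its voxel spacing in millimetres.
#'
#' @param suv 3-D numeric array of non-negative SUVs.
#' @param spacing numeric length-3 vector, voxel edge length in mm along
#'   each array dimension; strictly positive.
#' @return an object of class `pet_volume` with fields `suv`, `spacing`.
#' @export
pet_volume <- function(suv, spacing) {
  if (!is.array(suv) || length(dim(suv)) != 3L)
    stop("`suv` must be a 3-D array")
  if (length(suv) == 0L) stop("`suv` must be non-empty")
  if (any(!is.finite(suv)) || any(suv < 0))
    stop("`suv` must be finite and non-negative")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive numbers (mm)")
  structure(list(suv = suv, spacing = spacing), class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  cat("PET volume:", paste(dim(x$suv), collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing, 4), collapse = " x "),
      "mm, SUV range", signif(min(x$suv), 4), "-", signif(max(x$suv), 4), "\n")
  invisible(x)
}

#' Binary volume-of-interest mask
#'
#' @param mask 3-D logical array, same shape as its companion volume.
#' @return an object of class `voi_mask`.
#' @export
voi_mask <- function(mask) {
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask))
    stop("`mask` must be a 3-D logical array")
  if (anyNA(mask)) stop("`mask` must not contain NA")
  structure(list(mask = mask), class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat("VOI mask:", paste(dim(x$mask), collapse = " x "),
      "voxels,", sum(x$mask), "in mask\n")
  invisible(x)
}

check_same_grid <- function(volume, mask) {
  stopifnot(inherits(volume, "pet_volume"), inherits(mask, "voi_mask"))
  if (!identical(dim(volume$suv), dim(mask$mask)))
    stop("volume and mask must share the same grid shape")
}

#' Read or write PET volumes and VOI masks as NIfTI
#'
#' Thin wrappers around RNifti keeping the voxel spacing in the header.
#' Masks are stored as 0/1 integer volumes.
#'
#' @param x a [pet_volume()] or [voi_mask()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @param spacing voxel spacing to record for a mask, in mm.
#' @return the written path (writers) or the reconstructed object
#'   (readers).
#' @export
write_pet_volume <- function(x, path) {
  stopifnot(inherits(x, "pet_volume"))
  img <- RNifti::asNifti(x$suv)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_pet_volume
#' @export
read_pet_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  pet_volume(arr, RNifti::pixdim(img)[1:3])
}

#' @rdname write_pet_volume
#' @export
write_voi_mask <- function(x, path, spacing = c(1, 1, 1)) {
  stopifnot(inherits(x, "voi_mask"))
  img <- RNifti::asNifti(array(as.integer(x$mask), dim = dim(x$mask)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_pet_volume
#' @export
read_voi_mask <- function(path) {
  img <- RNifti::readNifti(path)
  voi_mask(array(as.numeric(img) > 0.5, dim = dim(img)))
}
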