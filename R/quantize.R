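#' Quantize in-mask SUVs to discrete grey levels
#'
#' Linear equal-width binning of the in-mask SUV range into `n_levels`
#' levels (1..Ng), the precondition for all texture matrices.  A constant
#' region maps entirely to level 1.
#'
#' @param volume a [pet_volume()].
#' @param mask a non-empty [voi_mask()] on the same grid.
#' @param n_levels number of grey levels Ng (default 64).
#' @return an object of class `quantized_voi` with fields `levels` (an
#'   integer array, NA outside the mask) and `n_levels`.
#' @export
quantize_voi <- function(volume, mask, n_levels = 64L) {
  check_same_grid(volume, mask)
  n_levels <- as.integer(n_levels)
  stopifnot(length(n_levels) == 1L, n_levels >= 1L)
  idx <- which(mask$mask)
  if (!length(idx)) stop("mask is empty")
  vals <- volume$suv[idx]
  lev <- array(NA_integer_, dim(volume$suv))
  rng <- max(vals) - min(vals)
  if (rng == 0) {
    lev[idx] <- 1L
  } else {
    lev[idx] <- pmin(floor((vals - min(vals)) / rng * n_levels) + 1L,
                     n_levels)
  }
  structure(list(levels = lev, n_levels = n_levels),
            class = "quantized_voi")
}

# Build a quantized_voi directly from an integer level array (levels in
# 1..n_levels, NA outside the mask).  Used by tests and oracles.
#' @rdname quantize_voi
#' @param levels integer array of grey levels (NA outside the mask).
#' @export
quantized_voi <- function(levels, n_levels = max(levels, na.rm = TRUE)) {
  if (!is.array(levels)) stop("`levels` must be an array")
  if (length(dim(levels)) == 2L) dim(levels) <- c(dim(levels), 1L)
  lv <- levels[!is.na(levels)]
  if (!length(lv)) stop("no in-mask voxels")
  if (any(lv < 1L) || any(lv > n_levels)) stop("levels outside 1..Ng")
  structure(list(levels = array(as.integer(levels), dim(levels)),
                 n_levels = as.integer(n_levels)),
            class = "quantized_voi")
}
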