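#' Conventional PET metrics inside a VOI
#'
#' Computes the five conventional PET parameters over the in-mask voxels:
#' SUVmax, SUVmean, SUVpeak, metabolic tumour volume (MTV, cm^3) and
#' total lesion glycolysis (TLG = SUVmean x MTV).  SUVpeak is the mean
#' SUV inside a 1-cm^3 sphere (radius 6.204 mm) centred on the hottest
#' in-mask voxel; the sphere is clipped to the grid and is not restricted
#' to the mask, matching the usual workstation definition.
#'
#' @param volume a [pet_volume()].
#' @param mask a [voi_mask()] on the same grid; must be non-empty.
#' @return named numeric vector `SUVmax`, `SUVmean`, `SUVpeak`, `MTV`,
#'   `TLG`.
#' @export
conventional_metrics <- function(volume, mask) {
  check_same_grid(volume, mask)
  idx <- which(mask$mask)
  if (!length(idx)) stop("mask is empty")
  suv <- volume$suv
  sp <- volume$spacing
  vals <- suv[idx]
  voxel_cm3 <- prod(sp) / 1000
  mtv <- length(vals) * voxel_cm3
  suv_mean <- mean(vals)

  # SUVpeak: 1-cm^3 sphere on the hottest in-mask voxel
  hot <- idx[which.max(vals)]
  d <- dim(suv)
  ctr <- arrayInd(hot, d)[1, ]
  r_mm <- (3 * 1000 / (4 * pi))^(1 / 3)
  half <- ceiling(r_mm / sp)
  rr <- max(1, ctr[1] - half[1]):min(d[1], ctr[1] + half[1])
  cc <- max(1, ctr[2] - half[2]):min(d[2], ctr[2] + half[2])
  ss <- max(1, ctr[3] - half[3]):min(d[3], ctr[3] + half[3])
  box <- expand.grid(r = rr, c = cc, s = ss)
  d2 <- ((box$r - ctr[1]) * sp[1])^2 + ((box$c - ctr[2]) * sp[2])^2 +
    ((box$s - ctr[3]) * sp[3])^2
  inside <- d2 <= r_mm^2
  lin <- box$r + (box$c - 1L) * d[1] + (box$s - 1L) * d[1] * d[2]
  suv_peak <- mean(suv[lin[inside]])

  c(SUVmax = max(vals), SUVmean = suv_mean, SUVpeak = suv_peak,
    MTV = mtv, TLG = suv_mean * mtv)
}
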