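form_factor_feature_names <- c(
  "Volume", "SurfaceArea", "SurfaceToVolumeRatio", "Sphericity",
  "Compactness1", "Compactness2", "SphericalDisproportion",
  "Maximum3DDiameter", "Eccentricity")

# Count exposed voxel faces along one array dimension and return the
# total face area contribution.
exposed_faces <- function(mask, dim_axis, spacing) {
  d <- dim(mask)
  shift_out <- function(step) {
    # TRUE where the neighbour `step` along dim_axis is outside the mask
    idx <- lapply(seq_along(d), function(a) seq_len(d[a]))
    src <- idx
    nb <- array(FALSE, d)
    rngA <- idx[[dim_axis]]
    inside <- rngA + step >= 1L & rngA + step <= d[dim_axis]
    src[[dim_axis]] <- rngA[inside] + step
    dst <- idx
    dst[[dim_axis]] <- rngA[inside]
    nb[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
    mask & !nb
  }
  face_area <- prod(spacing[-dim_axis])
  (sum(shift_out(1L)) + sum(shift_out(-1L))) * face_area
}

#' Form-factor (shape) features of a binary mask
#'
#' Nine shape descriptors of the voxelised tumour: volume (mm^3),
#' surface area by voxel face counting (mm^2), their ratio, sphericity
#' (pi^(1/3) (6V)^(2/3) / A), Compactness1 (V / (sqrt(pi) A^(3/2))),
#' Compactness2 (36 pi V^2 / A^3), spherical disproportion (A / surface
#' of the volume-equivalent sphere), the maximum 3-D diameter (largest
#' distance between boundary-voxel centres, mm) and eccentricity
#' (sqrt(1 - lambda_min/lambda_max) of the voxel-coordinate covariance).
#'
#' Face counting measures the digital (staircase) surface; for a
#' rasterised ball it converges to 1.5x the smooth-sphere area, so the
#' sphericity of a large digital ball tends to 2/3, not 1.
#'
#' @param mask a non-empty [voi_mask()].
#' @param spacing voxel spacing in mm (length 3).
#' @return named numeric vector of 9 features.
#' @export
form_factor_features <- function(mask, spacing) {
  stopifnot(inherits(mask, "voi_mask"))
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  m <- mask$mask
  idx <- which(m, arr.ind = TRUE)
  if (!nrow(idx)) stop("mask is empty")
  vol <- nrow(idx) * prod(spacing)
  area <- exposed_faces(m, 1L, spacing) + exposed_faces(m, 2L, spacing) +
    exposed_faces(m, 3L, spacing)
  r_eq <- (3 * vol / (4 * pi))^(1 / 3)
  sphericity <- pi^(1 / 3) * (6 * vol)^(2 / 3) / area
  # maximum diameter over boundary voxels (a voxel with any exposed face)
  bnd <- m
  for (ax in 1:3) {
    d <- dim(m)
    idx_all <- lapply(d, seq_len)
    for (stp in c(-1L, 1L)) {
      nb <- array(FALSE, d)
      rng <- idx_all[[ax]]
      inside <- rng + stp >= 1L & rng + stp <= d[ax]
      src <- idx_all; src[[ax]] <- rng[inside] + stp
      dst <- idx_all; dst[[ax]] <- rng[inside]
      nb[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
      bnd <- bnd | (m & !nb)
    }
  }
  bidx <- which(m & bnd, arr.ind = TRUE)
  co <- sweep(bidx, 2L, spacing, `*`)
  max_diam <- if (nrow(co) < 2L) 0 else {
    if (nrow(co) > 4000L) co <- co[sample.int(nrow(co), 4000L), ]
    max(dist(co))
  }
  co_all <- sweep(idx, 2L, spacing, `*`)
  ecc <- if (nrow(co_all) < 2L) 0 else {
    ev <- eigen(stats::cov(co_all), symmetric = TRUE,
                only.values = TRUE)$values
    ev <- pmax(ev, 0)
    if (ev[1] <= 0) 0 else sqrt(1 - min(ev) / max(ev))
  }
  c(Volume = vol, SurfaceArea = area, SurfaceToVolumeRatio = area / vol,
    Sphericity = sphericity,
    Compactness1 = vol / (sqrt(pi) * area^1.5),
    Compactness2 = 36 * pi * vol^2 / area^3,
    SphericalDisproportion = area / (4 * pi * r_eq^2),
    Maximum3DDiameter = max_diam, Eccentricity = ecc)
}
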