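# In-plane direction vectors (row, col) for the four texture angles.
# Directions are applied slice-wise (axial planes) because PET axial
# spacing differs from in-plane spacing and the feature names carry 2-D
# angle labels.
glcm_angles <- c(0L, 45L, 90L, 135L)

angle_step <- function(angle) {
  switch(as.character(angle),
         "0"   = c(0L, 1L),
         "45"  = c(-1L, 1L),
         "90"  = c(-1L, 0L),
         "135" = c(-1L, -1L),
         stop("angle must be one of 0, 45, 90, 135"))
}

# Symmetric, normalised grey-level co-occurrence matrix pooled over all
# axial slices.  Returns NULL when no in-mask voxel pair exists at this
# direction/offset.
glcm_matrix <- function(q, angle, offset) {
  stopifnot(inherits(q, "quantized_voi"))
  lev <- q$levels
  ng <- q$n_levels
  d <- dim(lev)
  st <- angle_step(angle) * as.integer(offset)
  r_src <- seq_len(d[1])
  r_src <- r_src[r_src + st[1] >= 1L & r_src + st[1] <= d[1]]
  c_src <- seq_len(d[2])
  c_src <- c_src[c_src + st[2] >= 1L & c_src + st[2] <= d[2]]
  if (!length(r_src) || !length(c_src)) return(NULL)
  a <- lev[r_src, c_src, , drop = FALSE]
  b <- lev[r_src + st[1], c_src + st[2], , drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NULL)
  ii <- a[ok]
  jj <- b[ok]
  counts <- matrix(tabulate(ii + ng * (jj - 1L), nbins = ng * ng), ng, ng)
  counts <- counts + t(counts)        # symmetrise
  counts / sum(counts)
}

glcm_feature_names <- c(
  "GLCMEnergy", "GLCMEntropy", "Inertia", "Correlation",
  "InverseDifferenceMoment", "ClusterShade", "ClusterProminence",
  "HaralickCorrelation")

# Eight co-occurrence features from a symmetric normalised matrix P.
# Degenerate grey-level variance makes Correlation and
# HaralickCorrelation undefined; both are reported as 0 with a warning.
glcm_features_from_matrix <- function(p) {
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  marg <- rowSums(p)                  # symmetric: row and col marginals equal
  mu <- sum(seq_len(ng) * marg)
  s2 <- sum((seq_len(ng) - mu)^2 * marg)
  energy <- sum(p^2)
  pp <- p[p > 0]
  entropy <- -sum(pp * log2(pp))
  inertia <- sum(p * (i - j)^2)
  idm <- sum(p / (1 + (i - j)^2))
  shade <- sum(p * (i + j - 2 * mu)^3)
  prom <- sum(p * (i + j - 2 * mu)^4)
  if (s2 <= 0) {
    warning("zero grey-level variance: Correlation and ",
            "HaralickCorrelation reported as 0", call. = FALSE)
    corr <- 0
    hcorr <- 0
  } else {
    corr <- sum((i - mu) * (j - mu) * p) / s2
    hcorr <- (sum(i * j * p) - mu^2) / s2
  }
  c(GLCMEnergy = energy, GLCMEntropy = entropy, Inertia = inertia,
    Correlation = corr, InverseDifferenceMoment = idm,
    ClusterShade = shade, ClusterProminence = prom,
    HaralickCorrelation = hcorr)
}

#' Grey-level co-occurrence features at one direction and offset
#'
#' Builds the symmetric, normalised co-occurrence matrix over in-plane
#' voxel pairs (both voxels in-mask) at the given angle and offset,
#' pooled across axial slices, and returns the eight co-occurrence
#' features: GLCMEnergy (sum P^2), GLCMEntropy (-sum P log2 P), Inertia
#' (sum P (i-j)^2), Correlation, InverseDifferenceMoment, ClusterShade,
#' ClusterProminence and HaralickCorrelation.
#'
#' If no voxel pair exists at the requested direction/offset all eight
#' features are reported as 0 with a warning.
#'
#' @param q a [quantize_voi()] result.
#' @param angle one of 0, 45, 90, 135 (degrees, in-plane).
#' @param offset pair distance in voxels (the catalogue uses 1, 4, 7).
#' @return named numeric vector of 8 features.
#' @export
glcm_features <- function(q, angle, offset) {
  p <- glcm_matrix(q, angle, offset)
  if (is.null(p)) {
    warning("no voxel pair at angle ", angle, ", offset ", offset,
            "; GLCM features reported as 0", call. = FALSE)
    out <- rep(0, length(glcm_feature_names))
    names(out) <- glcm_feature_names
    return(out)
  }
  glcm_features_from_matrix(p)
}
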