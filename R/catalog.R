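texture_offsets <- c(1L, 4L, 7L)

texture_block_names <- function(bases) {
  out <- character(0)
  for (off in texture_offsets) {
    for (b in bases) {
      out <- c(out,
               paste0(b, "_angle", glcm_angles, "_offset", off),
               paste0(b, "_AllDirection_offset", off),
               paste0(b, "_AllDirection_offset", off, "_SD"))
    }
  }
  out
}

#' The 401-feature radiomics catalogue
#'
#' Fixed names, families and order of every feature produced by
#' [extract_all()]: 5 conventional, 42 histogram, 144 co-occurrence
#' (8 base features x 3 offsets x (4 angles + AllDirection mean +
#' AllDirection SD)), 180 run-length (10 x 3 x 6), 21 zone-size and
#' 9 form-factor features.  "AllDirection" is the mean of the four
#' per-angle values and the "_SD" suffix their population standard
#' deviation (divisor 4).  The catalogue ships as versioned JSON in
#' `inst/extdata/feature_catalog.json`; [write_feature_catalog()]
#' regenerates that file.
#'
#' @return a data.frame with columns `name` and `family`, 401 rows.
#' @export
#' @examples
#' table(feature_catalog()$family)
feature_catalog <- function() {
  fam <- function(names, family) data.frame(name = names, family = family)
  cat <- rbind(
    fam(c("SUVmax", "SUVmean", "SUVpeak", "MTV", "TLG"), "conventional"),
    fam(histogram_feature_names, "histogram"),
    fam(texture_block_names(glcm_feature_names), "glcm"),
    fam(texture_block_names(glrlm_feature_names), "glrlm"),
    fam(glzsm_feature_names, "glzsm"),
    fam(form_factor_feature_names, "form_factor"))
  counts <- table(factor(cat$family, levels = c(
    "conventional", "histogram", "glcm", "glrlm", "glzsm", "form_factor")))
  stopifnot(identical(as.integer(counts), c(5L, 42L, 144L, 180L, 21L, 9L)),
            nrow(cat) == 401L, !anyDuplicated(cat$name))
  cat
}

#' @rdname feature_catalog
#' @param path destination for the JSON catalogue.
#' @export
write_feature_catalog <- function(path) {
  cat <- feature_catalog()
  jsonlite::write_json(
    list(version = "1.0",
         n_levels_default = 64L,
         direction_convention = paste(
           "2-D in-plane directions pooled slice-wise;",
           "AllDirection = mean over 4 angles, _SD = population SD"),
         quantile_convention = "linear interpolation (type 7)",
         features = cat),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Mean and population SD (divisor N) across the four angle values of a
# feature matrix (rows = angles, cols = base features).
pool_directions <- function(m) {
  mu <- colMeans(m)
  sdp <- sqrt(colMeans(sweep(m, 2L, mu)^2))
  list(mean = mu, sd = sdp)
}

#' Extract the full 401-feature vector from a segmented PET tumour
#'
#' Concatenates, in catalogue order, the conventional metrics, histogram
#' features, co-occurrence and run-length features at offsets 1/4/7 for
#' the four in-plane angles plus their AllDirection mean and SD,
#' zone-size features and form-factor features.  Identical input yields
#' a bit-identical vector.
#'
#' @param volume a [pet_volume()].
#' @param mask a non-empty [voi_mask()] on the same grid (normally from
#'   [segment_voi()]).
#' @param n_levels grey levels for quantization (default 64).
#' @return named numeric vector of exactly 401 features, ordered as in
#'   [feature_catalog()].
#' @export
extract_all <- function(volume, mask, n_levels = 64L) {
  conv <- conventional_metrics(volume, mask)
  hist <- histogram_features(volume, mask)
  q <- quantize_voi(volume, mask, n_levels)

  glcm_vals <- numeric(0)
  for (off in texture_offsets) {
    per_angle <- t(vapply(glcm_angles,
                          function(a) glcm_features(q, a, off),
                          numeric(length(glcm_feature_names))))
    pooled <- pool_directions(per_angle)
    for (bi in seq_along(glcm_feature_names)) {
      b <- glcm_feature_names[bi]
      v <- c(per_angle[, bi], pooled$mean[bi], pooled$sd[bi])
      names(v) <- c(paste0(b, "_angle", glcm_angles, "_offset", off),
                    paste0(b, "_AllDirection_offset", off),
                    paste0(b, "_AllDirection_offset", off, "_SD"))
      glcm_vals <- c(glcm_vals, v)
    }
  }

  # run-length features do not depend on the offset label: compute once
  # per angle and replicate across the three offset blocks
  rl_per_angle <- t(vapply(glcm_angles,
                           function(a) glrlm_features(q, a),
                           numeric(length(glrlm_feature_names))))
  rl_pooled <- pool_directions(rl_per_angle)
  glrlm_vals <- numeric(0)
  for (off in texture_offsets) {
    for (bi in seq_along(glrlm_feature_names)) {
      b <- glrlm_feature_names[bi]
      v <- c(rl_per_angle[, bi], rl_pooled$mean[bi], rl_pooled$sd[bi])
      names(v) <- c(paste0(b, "_angle", glcm_angles, "_offset", off),
                    paste0(b, "_AllDirection_offset", off),
                    paste0(b, "_AllDirection_offset", off, "_SD"))
      glrlm_vals <- c(glrlm_vals, v)
    }
  }

  out <- c(conv, hist, glcm_vals, glrlm_vals, glzsm_features(q),
           form_factor_features(mask, volume$spacing))
  cat_names <- feature_catalog()$name
  if (!identical(names(out), cat_names))
    stop("internal error: feature vector does not match the catalogue")
  out
}
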