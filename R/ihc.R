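#' Stain-pixel summary
#'
#' Pixel-area counts per staining-intensity class, as reported by
#' densitometric IHC software.  `n_background` records pixels excluded
#' as non-tissue so that counts are conserved.
#'
#' @param n_strong,n_moderate,n_weak,n_negative non-negative pixel
#'   counts; the classified total must be positive.
#' @param n_background excluded background pixels (default 0).
#' @return an object of class `stain_summary`.
#' @export
stain_summary <- function(n_strong, n_moderate, n_weak, n_negative,
                          n_background = 0) {
  counts <- c(n_strong = n_strong, n_moderate = n_moderate,
              n_weak = n_weak, n_negative = n_negative,
              n_background = n_background)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("pixel counts must be non-negative integers")
  if (sum(counts[1:4]) <= 0) stop("no classified tissue pixels")
  structure(as.list(counts), class = "stain_summary")
}

# Ruifrok-Johnston H-DAB stain optical-density vectors (rows:
# hematoxylin, DAB, residual), unit-normalised.
hdab_stain_matrix <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.269, 0.568, 0.778)
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  m <- rbind(hematoxylin = h / sqrt(sum(h^2)),
             dab = d / sqrt(sum(d^2)),
             residual = r / sqrt(sum(r^2)))
  m
}

#' Classify stained-tissue pixels from an RGB IHC tile
#'
#' Colour-deconvolves the tile into hematoxylin and DAB optical
#' densities using the standard H-DAB stain vectors, then counts pixels
#' as strong/moderate/weak positive (DAB density at or above `dab_min`,
#' split by cuts that default to equal thirds of the observed positive
#' density range), negative (hematoxylin-dominant nuclei) or background
#' (low density in both channels, excluded from all counts).
#'
#' @param tile RGB array `height x width x 3` with values in `[0, 1]`
#'   (values in 0..255 are rescaled).
#' @param dab_min minimum DAB optical density counted as positive.
#' @param hema_min minimum hematoxylin optical density counted as
#'   nuclear (negative) tissue.
#' @param cuts optional length-2 increasing vector of DAB-density cuts
#'   separating weak/moderate/strong; `NULL` (default) uses equal
#'   thirds of `[dab_min, max observed positive density]`.
#' @return a [stain_summary()].
#' @export
classify_pixels <- function(tile, dab_min = 0.15, hema_min = 0.15,
                            cuts = NULL) {
  if (!is.array(tile) || length(dim(tile)) != 3L || dim(tile)[3] != 3L)
    stop("`tile` must be an RGB array (height x width x 3)")
  if (length(tile) == 0L) stop("empty tile")
  v <- tile
  if (max(v) > 1) v <- v / 255
  od <- -log10(pmax(matrix(v, ncol = 3L), 1e-6))
  conc <- od %*% solve(hdab_stain_matrix())
  ch <- conc[, 1]
  cd <- conc[, 2]
  positive <- cd >= dab_min
  negative <- !positive & ch >= hema_min
  if (!any(positive) && !any(negative))
    stop("tile contains no tissue (all pixels below stain thresholds)")
  n_bg <- sum(!positive & !negative)
  if (any(positive)) {
    if (is.null(cuts)) {
      hi <- max(cd[positive])
      cuts <- dab_min + (hi - dab_min) * c(1, 2) / 3
    }
    stopifnot(length(cuts) == 2L, !is.unsorted(cuts))
    n_strong <- sum(cd >= cuts[2] & positive)
    n_moderate <- sum(cd >= cuts[1] & cd < cuts[2] & positive)
    n_weak <- sum(positive & cd < cuts[1])
  } else {
    n_strong <- n_moderate <- n_weak <- 0L
  }
  stain_summary(n_strong, n_moderate, n_weak, sum(negative), n_bg)
}

#' Read an RGB IHC tile from PNG or TIFF
#'
#' @param path image path; format inferred from the extension.
#' @return RGB array `height x width x 3` in `[0, 1]`.
#' @export
read_ihc_tile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = {
                  if (!requireNamespace("png", quietly = TRUE))
                    stop("reading PNG tiles requires the 'png' package")
                  png::readPNG(path)
                },
                tif = ,
                tiff = {
                  if (!requireNamespace("tiff", quietly = TRUE))
                    stop("reading TIFF tiles requires the 'tiff' package")
                  tiff::readTIFF(path)
                },
                stop("unsupported tile format: ", ext))
  if (length(dim(img)) == 3L && dim(img)[3] >= 3L)
    img <- img[, , 1:3, drop = FALSE]
  img
}

#' Positive-area fraction and H-score categories of a stain summary
#'
#' The positive fraction is the positive pixel area over all classified
#' tissue pixels.  The percentage category follows the printed cuts
#' (0: none; +1: <5%; +2: 5-20%; +3: 21-50%; +4: >50%) and the intensity
#' category is the positive class with the largest area (ties broken
#' toward the higher intensity; 0 when nothing is positive).
#'
#' @param summary a [stain_summary()].
#' @return list with `positive_fraction`, `percentage_category`,
#'   `intensity_category`.
#' @export
positivity <- function(summary) {
  stopifnot(inherits(summary, "stain_summary"))
  pos <- summary$n_strong + summary$n_moderate + summary$n_weak
  total <- pos + summary$n_negative
  frac <- pos / total
  pct <- if (pos == 0) 0L
  else if (frac < 0.05) 1L
  else if (frac <= 0.20) 2L
  else if (frac <= 0.50) 3L
  else 4L
  intensity <- if (pos == 0) 0L else {
    counts <- c(summary$n_weak, summary$n_moderate, summary$n_strong)
    max(which(counts == max(counts)))
  }
  list(positive_fraction = frac, percentage_category = pct,
       intensity_category = as.integer(intensity))
}

#' H-score and expression group
#'
#' H-score = staining-intensity category (0-3) x positive-percentage
#' category (0-4), range 0..12, grouped into negative/weak (H-score
#' 0-2), moderate (3, 4, 6) and strong (8, 9, 12) expression.
#'
#' @param intensity_category integer 0..3.
#' @param percentage_category integer 0..4.
#' @return list of class `h_score` with `value`, the two categories,
#'   `group` (0/1/2) and `group_label`.
#' @export
#' @examples
#' h_score(3, 4)$value  # 12, strong group
h_score <- function(intensity_category, percentage_category) {
  ic <- intensity_category
  pc <- percentage_category
  if (length(ic) != 1L || length(pc) != 1L ||
      ic != round(ic) || pc != round(pc) ||
      ic < 0 || ic > 3 || pc < 0 || pc > 4)
    stop("intensity_category must be 0..3 and percentage_category 0..4")
  value <- as.integer(ic * pc)
  group <- expression_group(value)
  structure(list(value = value,
                 intensity_category = as.integer(ic),
                 percentage_category = as.integer(pc),
                 group = group,
                 group_label = c("negative_or_weak", "moderate",
                                 "strong")[group + 1L]),
            class = "h_score")
}

#' @rdname h_score
#' @param value an H-score value 0..12.
#' @export
expression_group <- function(value) {
  stopifnot(length(value) >= 1L, all(value >= 0), all(value <= 12))
  # printed sets {1,2} / {3,4,6} / {8,9,12}; 0 joins the negative group
  # and unreachable values fall to the nearest printed boundary below
  as.integer(ifelse(value <= 2, 0L, ifelse(value <= 7, 1L, 2L)))
}
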