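histogram_feature_names <- c(
  "Min", "Max", "Range", "Mean", "Median", "Variance",
  "StandardDeviation", "MeanAbsoluteDeviation", "RelativeDeviation",
  "RMS", "Energy", "Entropy", "Uniformity", "Skewness", "Kurtosis",
  "Quantile0.025", "Quantile0.25", "Quantile0.5", "Quantile0.75",
  "Quantile0.975",
  paste0("Percentile", seq(5, 95, by = 5)),
  "Mode", "InterquartileRange", "CoefficientOfVariation")

#' First-order (histogram) features of the in-mask SUV distribution
#'
#' The 42-name roster: extremes and central moments, mean absolute
#' deviation and its mean-relative form, RMS/Energy, entropy and
#' uniformity over a 64-bin equal-width histogram of the in-mask range,
#' population skewness and excess kurtosis, the five quantiles
#' (including `Quantile0.025` used by the published Rad-score) and the
#' 19 percentiles 5..95 under the linear-interpolation convention
#' ([stats::quantile()] type 7), the histogram mode (bin midpoint, ties
#' to the lowest bin), interquartile range and coefficient of variation.
#' Skewness and kurtosis of a zero-variance sample are reported as 0
#' with a warning.
#'
#' @param volume a [pet_volume()].
#' @param mask a non-empty [voi_mask()] on the same grid.
#' @param n_bins histogram bin count for entropy/uniformity/mode
#'   (default 64).
#' @return named numeric vector of 42 features.
#' @export
histogram_features <- function(volume, mask, n_bins = 64L) {
  check_same_grid(volume, mask)
  x <- volume$suv[mask$mask]
  if (!length(x)) stop("mask is empty")
  n <- length(x)
  mu <- mean(x)
  rng <- max(x) - min(x)
  v <- if (n > 1) var(x) else 0
  s <- sqrt(v)
  m2 <- mean((x - mu)^2)
  if (m2 == 0) {
    if (n > 1)
      warning("zero-variance sample: skewness and kurtosis reported as 0",
              call. = FALSE)
    skew <- 0
    kurt <- 0
  } else {
    skew <- mean((x - mu)^3) / m2^1.5
    kurt <- mean((x - mu)^4) / m2^2 - 3
  }
  # histogram-based entropy/uniformity/mode
  if (rng == 0) {
    p <- 1
    mode_val <- x[1]
  } else {
    br <- seq(min(x), max(x), length.out = n_bins + 1L)
    cnt <- tabulate(pmin(findInterval(x, br, rightmost.closed = TRUE),
                         n_bins), nbins = n_bins)
    p <- cnt[cnt > 0] / n
    mids <- (br[-1] + br[-(n_bins + 1L)]) / 2
    mode_val <- mids[which.max(cnt)]
  }
  qs <- quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975), type = 7,
                 names = FALSE)
  pctl <- quantile(x, seq(5, 95, by = 5) / 100, type = 7, names = FALSE)
  out <- c(
    min(x), max(x), rng, mu, quantile(x, 0.5, type = 7, names = FALSE),
    v, s, mean(abs(x - mu)),
    if (mu != 0) mean(abs(x - mu)) / mu else 0,
    sqrt(mean(x^2)), sum(x^2), -sum(p * log2(p)), sum(p^2), skew, kurt,
    qs, pctl, mode_val, qs[4] - qs[2],
    if (mu != 0) s / mu else 0)
  names(out) <- histogram_feature_names
  out
}
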