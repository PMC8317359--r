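#' Mann-Whitney U test with SPSS-style output
#'
#' Returns the statistics the clinical literature tabulates: U (the
#' smaller of the two pair-count statistics), Wilcoxon W (the rank sum
#' of the group attaining that U, so W = U + n_k(n_k+1)/2), the
#' normal-approximation z with tie correction and a 0.5 continuity
#' correction, and the two-sided p.
#'
#' @param x,y numeric samples (both non-empty).
#' @return list of class `mann_whitney_result` with `u`, `wilcoxon_w`,
#'   `z`, `p`, `n1`, `n2`.
#' @export
mann_whitney <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  stopifnot(length(x) >= 1L, length(y) >= 1L,
            all(is.finite(x)), all(is.finite(y)))
  n1 <- length(x)
  n2 <- length(y)
  nn <- n1 + n2
  rk <- rank(c(x, y))
  r1 <- sum(rk[seq_len(n1)])
  r2 <- sum(rk) - r1
  u1 <- r1 - n1 * (n1 + 1) / 2
  u2 <- r2 - n2 * (n2 + 1) / 2
  if (u1 <= u2) {
    u <- u1; w <- r1
  } else {
    u <- u2; w <- r2
  }
  mu <- n1 * n2 / 2
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term / (nn * (nn - 1)))
  if (sigma2 <= 0) {
    z <- 0
    p <- 1
  } else {
    sigma <- sqrt(sigma2)
    z <- if (u == mu) 0 else (u - mu + 0.5 * sign(mu - u)) / sigma
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  structure(list(u = u, wilcoxon_w = w, z = z, p = p, n1 = n1, n2 = n2),
            class = "mann_whitney_result")
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks for ties; p from t = rho sqrt((n-2)/(1-rho^2)) on n-2
#' degrees of freedom (p = 0 at |rho| = 1).
#'
#' @param x,y numeric vectors of equal length n >= 3; neither constant.
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (sd(x) == 0 || sd(y) == 0)
    stop("Spearman correlation undefined for a constant input")
  n <- length(x)
  rho <- cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Two-way random-effects, absolute-agreement, single-measure ICC
#'
#' ICC(2,1) from the standard mean-squares decomposition of a cases x 2
#' raters table; used to quantify how reproducible each radiomics
#' feature is across two independent readers' segmentations.
#'
#' @param ratings numeric matrix, cases in rows, exactly 2 rater
#'   columns, n >= 3 cases.
#' @return list with `icc` and the mean squares `msr`, `msc`, `mse`.
#' @export
icc_two_rater <- function(ratings) {
  m <- as.matrix(ratings)
  stopifnot(ncol(m) == 2L, nrow(m) >= 3L, all(is.finite(m)))
  n <- nrow(m)
  k <- 2L
  if (var(as.vector(m)) == 0)
    stop("zero total variance: ICC undefined")
  grand <- mean(m)
  rmean <- rowMeans(m)
  cmean <- colMeans(m)
  msr <- k * sum((rmean - grand)^2) / (n - 1)
  msc <- n * sum((cmean - grand)^2) / (k - 1)
  mse <- sum((m - outer(rmean, rep(1, k)) -
                outer(rep(1, n), cmean) + grand)^2) /
    ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  list(icc = icc, msr = msr, msc = msc, mse = mse)
}

#' Per-feature two-reader ICC summary
#'
#' @param reader1,reader2 numeric matrices (cases x features) holding
#'   the same features extracted from each reader's segmentations.
#' @param threshold reproducibility cut (default 0.75).
#' @return list with a data.frame `per_feature` (`feature`, `icc`; NA
#'   where the ICC is undefined) and `n_above_threshold`.
#' @export
icc_feature_summary <- function(reader1, reader2, threshold = 0.75) {
  stopifnot(identical(dim(reader1), dim(reader2)))
  feats <- colnames(reader1) %||% paste0("f", seq_len(ncol(reader1)))
  icc <- vapply(seq_len(ncol(reader1)), function(j) {
    tryCatch(icc_two_rater(cbind(reader1[, j], reader2[, j]))$icc,
             error = function(e) NA_real_)
  }, numeric(1))
  list(per_feature = data.frame(feature = feats, icc = icc),
       n_above_threshold = sum(icc > threshold, na.rm = TRUE),
       threshold = threshold)
}
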