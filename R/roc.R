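# Pairwise win matrix psi(pos_i, neg_j): 1 win, 0.5 tie, 0 loss.
psi_matrix <- function(scores, labels) {
  y <- as.integer(labels != 0)
  pos <- scores[y == 1L]
  neg <- scores[y == 0L]
  if (!length(pos) || !length(neg))
    stop("both classes must be present")
  outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
}

#' ROC analysis of a continuous score against a binary label
#'
#' AUC by the Mann-Whitney identity with half credit for ties; variance
#' and 95% CI from the DeLong structural components (the CI is computed
#' on the logit scale for stability near 1 and clipped to `[0, 1]`);
#' `p_vs_chance` tests AUC = 0.5 with the same variance; sensitivity and
#' specificity are reported at the Youden-optimal threshold (prediction
#' positive when score >= threshold; ties resolved toward the higher
#' sensitivity).
#'
#' @param scores numeric predictor (higher = more suspicious).
#' @param labels binary outcome (0/1 or logical); both classes present.
#' @param conf confidence level (default 0.95).
#' @return list of class `roc_result`: `auc`, `ci95`, `sensitivity`,
#'   `specificity`, `threshold`, `p_vs_chance`, `var_auc`, `n_pos`,
#'   `n_neg`.
#' @export
roc_auc <- function(scores, labels, conf = 0.95) {
  psi <- psi_matrix(scores, labels)
  m <- nrow(psi)
  n <- ncol(psi)
  auc <- mean(psi)
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  var_auc <- (if (m > 1) var(v10) / m else 0) +
    (if (n > 1) var(v01) / n else 0)
  zq <- qnorm(1 - (1 - conf) / 2)
  if (var_auc <= 0) {
    ci <- c(auc, auc)
  } else {
    at <- min(max(auc, 1e-6), 1 - 1e-6)
    se_l <- sqrt(var_auc) / (at * (1 - at))
    ci <- plogis(qlogis(at) + c(-1, 1) * zq * se_l)
    ci <- c(min(ci[1], auc), max(ci[2], auc))
  }
  p_chance <- if (var_auc <= 0) {
    if (auc == 0.5) 1 else 0
  } else 2 * pnorm(-abs((auc - 0.5) / sqrt(var_auc)))

  y <- as.integer(labels != 0)
  pos <- scores[y == 1L]
  neg <- scores[y == 0L]
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(sens[best])]
  structure(list(auc = auc, ci95 = ci, sensitivity = sens[best],
                 specificity = spec[best], threshold = thr[best],
                 p_vs_chance = p_chance, var_auc = var_auc,
                 n_pos = m, n_neg = n),
            class = "roc_result")
}

#' DeLong test for two correlated ROC curves
#'
#' Paired comparison of the AUCs of two scores measured on the same
#' cases, using the covariance of the DeLong structural components;
#' two-sided p from the standard normal.  A zero-variance difference
#' with equal AUCs returns z = 0, p = 1.
#'
#' @param scores_a,scores_b two scores on the same cases.
#' @param labels shared binary outcome.
#' @return list of class `delong_result`: `auc_a`, `auc_b`,
#'   `auc_difference`, `z`, `p`.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(labels))
  pa <- psi_matrix(scores_a, labels)
  pb <- psi_matrix(scores_b, labels)
  m <- nrow(pa)
  n <- ncol(pa)
  auc_a <- mean(pa)
  auc_b <- mean(pb)
  diff <- auc_a - auc_b
  d10 <- rowMeans(pa) - rowMeans(pb)
  d01 <- colMeans(pa) - colMeans(pb)
  var_diff <- (if (m > 1) var(d10) / m else 0) +
    (if (n > 1) var(d01) / n else 0)
  if (var_diff <= 0) {
    z <- if (diff == 0) 0 else sign(diff) * Inf
    p <- if (diff == 0) 1 else 0
  } else {
    z <- diff / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(auc_a = auc_a, auc_b = auc_b, auc_difference = diff,
                 z = z, p = p),
            class = "delong_result")
}
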