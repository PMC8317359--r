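#' Diagnostic plots for an evaluation report
#'
#' Base-graphics companions to [run_pipeline()]: overlaid ROC curves of
#' the three models on one split, a Rad-score boxplot by LVSI status,
#' and a histogram of the per-feature two-reader ICC values.
#'
#' @param report an `eval_report`.
#' @param split which split to plot (`"train"`, `"test"`,
#'   `"external"`).
#' @export
plot_roc_curves <- function(report, split = "train") {
  stopifnot(inherits(report, "eval_report"))
  pats <- report$patients
  rows <- pats$split == split
  y <- pats$lvsi[rows]
  scores <- list(radiomics = pats$rad_score[rows],
                 protein = pats$tnc_group[rows] + pats$cox2_group[rows],
                 combined = NULL)
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = paste("ROC,", split, "set"))
  cols <- c(radiomics = "blue", protein = "red", combined = "orange")
  for (mn in names(report$models)) {
    cols_m <- switch(mn, radiomics = "rad_score",
                     protein = c("tnc", "cox2"),
                     combined = c("rad_score", "tnc", "cox2"))
    px <- data.frame(rad_score = pats$rad_score[rows],
                     tnc = pats$tnc_group[rows],
                     cox2 = pats$cox2_group[rows])
    s <- predict_model_safe(report$models[[mn]],
                            px[, cols_m, drop = FALSE])
    thr <- c(-Inf, sort(unique(s)), Inf)
    sens <- vapply(thr, function(t) mean(s[y == 1] >= t), numeric(1))
    spec <- vapply(thr, function(t) mean(s[y == 0] < t), numeric(1))
    graphics::lines(1 - spec, sens, col = cols[mn], lwd = 2)
  }
  graphics::legend("bottomright", legend = names(report$models),
                   col = cols[names(report$models)], lwd = 2, bty = "n")
  invisible(report)
}

#' @rdname plot_roc_curves
#' @export
plot_radscore_box <- function(report) {
  stopifnot(inherits(report, "eval_report"))
  pats <- report$patients
  graphics::boxplot(rad_score ~ factor(lvsi, c(0, 1),
                                       c("non-LVSI", "LVSI")),
                    data = pats, ylab = "Rad-score", xlab = "")
  invisible(report)
}

#' @rdname plot_roc_curves
#' @export
plot_icc_histogram <- function(report) {
  stopifnot(inherits(report, "eval_report"))
  if (is.null(report$icc)) stop("report has no ICC sub-study")
  icc <- report$icc$per_feature$icc
  graphics::hist(icc[is.finite(icc)], breaks = 20,
                 main = "Two-reader feature reproducibility",
                 xlab = "ICC")
  graphics::abline(v = report$icc$threshold, col = "red", lty = 2)
  invisible(report)
}
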