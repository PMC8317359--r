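#' Maximum-likelihood logistic regression with Wald statistics
#'
#' Fits a binomial GLM by iteratively reweighted least squares
#' ([stats::glm()]) and reports, per term, the coefficient, standard
#' error (from the inverse observed information), Wald statistic
#' `(coef/SE)^2` and its chi-square(1) p-value — the layout of a
#' multivariate logistic regression table.  Complete or quasi-complete
#' separation (non-convergence, or fitted probabilities driven to the
#' 0/1 boundary) is rejected with a diagnostic.  Constant (aliased)
#' columns are dropped with a note.
#'
#' @param x numeric matrix or data.frame of predictors (may have zero
#'   columns for an intercept-only model).
#' @param y binary outcome (0/1 or logical).
#' @return list of class `logistic_model`: `terms`, `coefficients`,
#'   `standard_errors`, `wald`, `p_values`, `dropped`, plus the
#'   underlying `fit`.
#' @export
fit_logistic <- function(x, y) {
  y <- as.integer(y != 0)
  x <- as.data.frame(x)
  stopifnot(nrow(x) == length(y) || ncol(x) == 0L)
  dat <- cbind(data.frame(.y = y), x)
  fit <- glm(.y ~ ., data = dat, family = binomial())
  if (!fit$converged)
    stop("logistic fit did not converge (possible separation)")
  eps <- 1e-8
  fv <- fitted(fit)
  if (any(fv < eps) || any(fv > 1 - eps))
    stop("fitted probabilities at the 0/1 boundary: ",
         "data are (quasi-)separated")
  cf <- coef(fit)
  dropped <- names(cf)[is.na(cf)]
  keep <- !is.na(cf)
  cf <- cf[keep]
  se <- sqrt(diag(stats::vcov(fit)))[names(cf)]
  wald <- (cf / se)^2
  pv <- pchisq(wald, df = 1, lower.tail = FALSE)
  structure(list(terms = names(cf), coefficients = unname(cf),
                 standard_errors = unname(se), wald = unname(wald),
                 p_values = unname(pv), dropped = dropped, fit = fit),
            class = "logistic_model")
}

#' @rdname fit_logistic
#' @param model a fitted `logistic_model`.
#' @param newx new predictor data with the training columns.
#' @return `predict_logistic`: predicted probabilities.
#' @export
predict_logistic <- function(model, newx) {
  stopifnot(inherits(model, "logistic_model"))
  unname(predict(model$fit, newdata = as.data.frame(newx),
                 type = "response"))
}

#' @export
print.logistic_model <- function(x, ...) {
  print(data.frame(term = x$terms, coefficient = x$coefficients,
                   se = x$standard_errors, wald = x$wald,
                   p = x$p_values))
  invisible(x)
}
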