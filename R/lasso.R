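#' Z-score standardisation fitted on training data
#'
#' Centres and scales every feature column to mean 0 and sample SD 1
#' (divisor n-1) using parameters estimated on the training table only;
#' any additional tables (testing, external) are transformed with the
#' training parameters.  Features with zero spread in the training data
#' are dropped from every table with a warning.
#'
#' @param train numeric matrix/data.frame of training features.
#' @param ... further tables to transform with the training parameters.
#' @return list with `train`, `others` (list of transformed tables),
#'   `center`, `scale`, `dropped`.
#' @export
zscore_fit_apply <- function(train, ...) {
  tr <- as.matrix(train)
  others <- lapply(list(...), as.matrix)
  ctr <- colMeans(tr)
  scl <- apply(tr, 2L, sd)
  bad <- !is.finite(scl) | scl < 1e-12
  dropped <- colnames(tr)[bad]
  if (any(bad)) {
    warning("dropping ", sum(bad), " zero-variance feature(s): ",
            paste(head(dropped, 5L), collapse = ", "),
            if (sum(bad) > 5L) ", ..." else "", call. = FALSE)
    tr <- tr[, !bad, drop = FALSE]
    others <- lapply(others, function(m) m[, !bad, drop = FALSE])
    ctr <- ctr[!bad]
    scl <- scl[!bad]
  }
  tf <- function(m) sweep(sweep(m, 2L, ctr), 2L, scl, `/`)
  list(train = tf(tr), others = lapply(others, tf),
       center = ctr, scale = scl, dropped = dropped)
}

#' LASSO configuration
#'
#' @param n_folds cross-validation folds (default 10).
#' @param lambda_grid optional decreasing penalty grid; by default 100
#'   log-spaced values from the analytic lambda_max (above which all
#'   coefficients shrink to zero) down four decades.
#' @param seed seed for the stratified fold assignment.
#' @return list of class `lasso_config`.
#' @export
lasso_config <- function(n_folds = 10L, lambda_grid = NULL, seed = 1L) {
  stopifnot(n_folds >= 2L)
  if (!is.null(lambda_grid))
    stopifnot(all(lambda_grid > 0), !is.unsorted(rev(lambda_grid)))
  structure(list(n_folds = as.integer(n_folds),
                 lambda_grid = lambda_grid, seed = as.integer(seed)),
            class = "lasso_config")
}

# Outcome-stratified fold labels, seeded.
stratified_folds <- function(y, n_folds, seed) {
  set.seed(seed)
  foldid <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  foldid
}

#' LASSO-penalised logistic feature selection
#'
#' L1-penalised logistic path (via glmnet) over the lambda grid; the
#' operating lambda minimises the mean binomial deviance in seeded,
#' outcome-stratified k-fold cross-validation, and the features with
#' non-zero coefficients at that lambda are returned together with the
#' full CV deviance profile.  Predictors are expected to be standardised
#' already (see [zscore_fit_apply()]); no further internal
#' standardisation is applied.
#'
#' @param x standardised numeric predictor matrix.
#' @param y binary outcome with both classes present.
#' @param config a [lasso_config()].
#' @return list of class `lasso_selection`: `selected`, `coefficients`
#'   (named, non-zero terms only), `intercept`, `lambda`,
#'   `cv_deviance` (data.frame lambda/deviance), `n_folds`.
#' @export
lasso_select <- function(x, y, config = lasso_config()) {
  x <- as.matrix(x)
  y <- as.integer(y != 0)
  if (length(unique(y)) < 2L)
    stop("outcome has a single class; cannot fit")
  stopifnot(nrow(x) == length(y))
  grid <- config$lambda_grid
  if (is.null(grid)) {
    lmax <- max(abs(crossprod(x, y - mean(y)))) / length(y)
    grid <- exp(seq(log(lmax), log(lmax * 1e-4), length.out = 100L))
  }
  foldid <- stratified_folds(y, config$n_folds, config$seed)
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                          lambda = grid, foldid = foldid,
                          standardize = FALSE,
                          type.measure = "deviance", thresh = 1e-9)
  lam <- cv$lambda.min
  cf <- as.matrix(coef(cv$glmnet.fit, s = lam))
  intercept <- cf[1L, 1L]
  beta <- cf[-1L, 1L]
  nz <- beta != 0
  structure(list(selected = names(beta)[nz],
                 coefficients = beta[nz],
                 intercept = intercept,
                 lambda = lam,
                 cv_deviance = data.frame(lambda = cv$lambda,
                                          deviance = cv$cvm),
                 n_folds = config$n_folds),
            class = "lasso_selection")
}
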