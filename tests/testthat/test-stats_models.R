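test_that("z-score normalisation uses training parameters everywhere", {
  tr <- matrix(c(1, 2, 3, 10, 20, 30), ncol = 2,
               dimnames = list(NULL, c("a", "b")))
  te <- matrix(c(2, 4, 20, 40), ncol = 2,
               dimnames = list(NULL, c("a", "b")))
  zs <- zscore_fit_apply(tr, te)
  # sample-SD convention: column [1,2,3] -> [-1, 0, 1]
  expect_equal(zs$train[, "a"], c(-1, 0, 1))
  expect_equal(colMeans(zs$train), c(a = 0, b = 0), tolerance = 1e-9)
  expect_equal(apply(zs$train, 2, sd), c(a = 1, b = 1), tolerance = 1e-9)
  # test value equal to the training mean maps to 0
  expect_equal(unname(zs$others[[1]][1, "a"]), 0)
  # refit on an already-standardised table leaves it unchanged
  zs2 <- zscore_fit_apply(zs$train)
  expect_equal(zs2$train, zs$train, tolerance = 1e-9)
  # zero-variance column dropped with a warning
  trc <- cbind(tr, cnst = c(5, 5, 5))
  expect_warning(zs3 <- zscore_fit_apply(trc), "zero-variance")
  expect_false("cnst" %in% colnames(zs3$train))
})

test_that("LASSO shrinkage bound, unpenalised limit and planted support", {
  set.seed(41)
  n <- 120
  x <- matrix(rnorm(n * 8), n, 8,
              dimnames = list(NULL, paste0("f", 1:8)))
  x <- scale(x)[, ]
  eta <- x[, 1] - x[, 2]
  y <- rbinom(n, 1, plogis(eta))

  # lambda at/above the analytic bound selects nothing
  lmax <- max(abs(crossprod(x, y - mean(y)))) / n
  sel_big <- lasso_select(x, y, lasso_config(
    lambda_grid = c(lmax * 2, lmax * 1.5), seed = 1))
  expect_length(sel_big$selected, 0L)

  # lambda -> 0 approaches the unpenalised logistic fit
  sel_small <- lasso_select(x, y, lasso_config(
    lambda_grid = c(1e-5, 1e-6), seed = 1))
  ml <- fit_logistic(x, y)
  expect_equal(unname(sel_small$coefficients[paste0("f", 1:8)]),
               ml$coefficients[-1], tolerance = 1e-3)

  # degenerate outcome rejected
  expect_error(lasso_select(x, rep(1, n)), "single class")

  # no selected feature refits to an exactly-zero unpenalised coefficient
  sel_cv <- lasso_select(x, y, lasso_config(seed = 2))
  if (length(sel_cv$selected)) {
    refit <- fit_logistic(x[, sel_cv$selected, drop = FALSE], y)
    expect_true(all(refit$coefficients[-1] != 0))
  }
})

test_that("published Rad-score model evaluates the printed formula", {
  m <- published_radscore_model()
  zero <- setNames(rep(0, 16), m$feature_names)
  expect_identical(rad_score(m, zero), -0.075)
  # unit vector on the first feature: -0.328 - 0.075
  one <- zero
  one["Correlation_angle45_offset7"] <- 1
  expect_equal(rad_score(m, one), -0.403, tolerance = 1e-12)
  # linearity: score(a+b) = score(a) + score(b) - intercept
  set.seed(3)
  a <- setNames(rnorm(16), m$feature_names)
  b <- setNames(rnorm(16), m$feature_names)
  expect_equal(rad_score(m, a + b),
               rad_score(m, a) + rad_score(m, b) - m$intercept,
               tolerance = 1e-12)
  expect_error(rad_score(m, zero[-1]), "missing")
})

test_that("logistic fit reproduces the closed-form two-point solution", {
  x <- data.frame(x = c(rep(1, 4), rep(-1, 4)))
  y <- c(1, 1, 1, 0, 0, 0, 0, 1)
  fit <- fit_logistic(x, y)
  expect_equal(fit$coefficients[match("x", fit$terms)], 0.5 * log(9),
               tolerance = 1e-6)
  expect_equal(fit$coefficients[match("(Intercept)", fit$terms)], 0,
               tolerance = 1e-9)
  expect_equal(fit$wald, (fit$coefficients / fit$standard_errors)^2)

  # constant predictor with balanced outcome: intercept 0, term dropped
  x0 <- data.frame(x = rep(0, 10))
  y0 <- rep(c(0, 1), 5)
  fit0 <- fit_logistic(x0, y0)
  expect_equal(fit0$coefficients[1], 0, tolerance = 1e-9)
  expect_true("x" %in% fit0$dropped)

  # complete separation rejected
  xs <- data.frame(x = c(-2, -1, 1, 2))
  expect_error(fit_logistic(xs, c(0, 0, 1, 1)), "separat")
})

test_that("null calibration: permuted labels rarely give small p-values", {
  set.seed(55)
  rejections <- 0L
  for (k in 1:20) {
    x <- matrix(rnorm(200), 200, 1, dimnames = list(NULL, "x"))
    y <- sample(rep(c(0L, 1L), 100))
    fit <- fit_logistic(x, y)
    if (fit$p_values[2] <= 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections, 2L)
})

test_that("ROC analysis: trivial cases and the swap example", {
  r <- roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)

  rc <- roc_auc(rep(2, 8), rep(c(0, 1), 4))
  expect_equal(rc$auc, 0.5)

  rs <- roc_auc(c(1, 3, 2, 4), c(0, 0, 1, 1))
  expect_equal(rs$auc, 0.75)

  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
  expect_true(r$ci95[1] <= r$auc && r$auc <= r$ci95[2])
})

test_that("AUC equals brute-force pair counting on random small fixtures", {
  set.seed(14)
  for (k in 1:25) {
    n <- sample(4:12, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- sample(seq_len(6), n, replace = TRUE) + runif(n) * 0.01
    expect_equal(roc_auc(s, y)$auc, oracle_auc(s, y), tolerance = 1e-12)
  }
})

test_that("ROC results agree with pROC as an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(26)
  s <- rnorm(60)
  y <- rbinom(60, 1, plogis(s))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  ours <- roc_auc(s, y)
  ref <- pROC::roc(y, s, quiet = TRUE, direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  expect_equal(ours$var_auc, as.numeric(pROC::var(ref)),
               tolerance = 1e-10)
  # paired DeLong test against pROC
  s2 <- s + rnorm(60, 0, 0.8)
  ours2 <- delong_compare(s, s2, y)
  ref2 <- pROC::roc.test(pROC::roc(y, s, quiet = TRUE, direction = "<"),
                         pROC::roc(y, s2, quiet = TRUE, direction = "<"),
                         method = "delong", paired = TRUE)
  expect_equal(ours2$p, as.numeric(ref2$p.value), tolerance = 1e-9)
})

test_that("DeLong comparison: identity, antisymmetry and degeneracy", {
  set.seed(7)
  s <- rnorm(20)
  y <- rep(c(0, 1), 10)
  same <- delong_compare(s, s, y)
  expect_equal(same$auc_difference, 0)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  s2 <- s + rnorm(20, 0, 0.5)
  ab <- delong_compare(s, s2, y)
  ba <- delong_compare(s2, s, y)
  expect_equal(ab$auc_difference, -ba$auc_difference)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
  expect_equal(sign(ab$z), sign(ab$auc_difference))
})

test_that("Mann-Whitney matches the SPSS conventions and edge cases", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$u, 0)
  expect_equal(mw$wilcoxon_w, mw$u + 2 * 3 / 2)

  x <- c(5, 6, 7)
  same <- mann_whitney(x, x)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1, tolerance = 0.01)

  # W = U + n_k(n_k+1)/2 for the group attaining the smaller U
  set.seed(18)
  a <- rnorm(9)
  b <- rnorm(5) + 1
  mw2 <- mann_whitney(a, b)
  expect_true(mw2$wilcoxon_w %in%
                (mw2$u + c(9 * 10 / 2, 5 * 6 / 2)))
  expect_true(mw2$u >= 0 && mw2$u <= 9 * 5)
})

test_that("Mann-Whitney normal approximation tracks the exact permutation law", {
  x <- c(10, 12, 11, 15, 13, 14)
  y <- c(12, 16, 17, 13, 18, 15)
  mw <- mann_whitney(x, y)
  expect_lt(abs(mw$p - oracle_mw_exact_p(x, y)), 0.01)
})

test_that("Spearman correlation handles monotone, reversed and tied data", {
  expect_equal(spearman_test(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_test(1:8, -(1:8))$rho, -1)
  expect_error(spearman_test(rep(1, 5), 1:5), "constant")

  # ties: compare with the direct rank formula
  x <- c(1, 2, 2, 3, 4, 5, 5, 6, 7, 8)
  y <- c(2, 1, 3, 3, 5, 4, 6, 6, 8, 7)
  st <- spearman_test(x, y)
  expect_equal(st$rho, cor(rank(x), rank(y)), tolerance = 1e-9)
  expect_equal(st$rho, cor(x, y, method = "spearman"), tolerance = 1e-9)
})

test_that("ICC(2,1): perfect agreement, null and variance-ratio regimes", {
  set.seed(61)
  base <- rnorm(20)
  expect_equal(icc_two_rater(cbind(base, base))$icc, 1)

  noise <- cbind(rnorm(1000), rnorm(1000))
  expect_lt(abs(icc_two_rater(noise)$icc), 0.1)

  # case SD 2, rater noise SD 1 -> ICC ~ 4/5
  cases <- rnorm(500, sd = 2)
  r <- cbind(cases + rnorm(500), cases + rnorm(500))
  expect_equal(icc_two_rater(r)$icc, 0.8, tolerance = 0.05)

  expect_error(icc_two_rater(matrix(1, 5, 2)), "zero total variance")

  summ <- icc_feature_summary(
    cbind(a = cases, b = rnorm(500)),
    cbind(a = cases + rnorm(500), b = rnorm(500)))
  expect_equal(summ$n_above_threshold, 1L)
})
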