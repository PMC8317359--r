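#' Pipeline run configuration
#'
#' Bundles everything one reproducible run needs: the simulation
#' configuration (or paths to pre-computed inputs), split ratio,
#' external-set size, feature-extraction parameters, the two-reader ICC
#' sub-study size, the master seed and an optional output directory.
#'
#' @param sim a [sim_config()] describing the synthetic cohort.
#' @param split_ratio training fraction for the random split.
#' @param n_external eligible patients reserved as an external
#'   validation set before splitting (default 26).
#' @param n_levels grey levels for texture quantization.
#' @param threshold_fraction VOI threshold as a fraction of SUVmax.
#' @param icc_cases training cases re-segmented by a simulated second
#'   reader for the ICC sub-study (0 disables it).
#' @param icc_second_fraction the second reader's segmentation
#'   threshold fraction.
#' @param seed master seed; every random stage derives its stream from
#'   it (see [derive_seed()]).
#' @param output_dir optional directory for CSV/JSON outputs.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       split_ratio = 0.7,
                       n_external = 26L,
                       n_levels = 64L,
                       threshold_fraction = 0.42,
                       icc_cases = 12L,
                       icc_second_fraction = 0.38,
                       seed = 1L,
                       output_dir = NULL) {
  stopifnot(inherits(sim, "sim_config"),
            split_ratio > 0, split_ratio < 1,
            n_external >= 0L, icc_cases >= 0L,
            threshold_fraction > 0, threshold_fraction < 1)
  structure(list(sim = sim, split_ratio = split_ratio,
                 n_external = as.integer(n_external),
                 n_levels = as.integer(n_levels),
                 threshold_fraction = threshold_fraction,
                 icc_cases = as.integer(icc_cases),
                 icc_second_fraction = icc_second_fraction,
                 seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

# Ridge-penalised logistic fit by Newton iterations (penalty on the
# slopes only); used as a fallback when the ML fit is separable.
ridge_logistic <- function(xm, y, lambda = 1e-2) {
  xx <- cbind(`(Intercept)` = 1, xm)
  p <- ncol(xx)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- rep(0, p)
  for (it in 1:100) {
    eta <- drop(xx %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- crossprod(xx, y - mu) - pen %*% beta
    hess <- crossprod(xx * w, xx) + pen
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  beta
}

# Fit one of the three models, falling back to a lightly ridge-penalised
# fit when the training data are separable (documented fallback; the
# strict ML fit is the default path).
fit_model_safe <- function(x, y) {
  tryCatch(fit_logistic(x, y), error = function(e) {
    xm <- as.matrix(x)
    beta <- ridge_logistic(xm, y)
    structure(list(terms = c("(Intercept)", colnames(xm)),
                   coefficients = unname(beta),
                   standard_errors = rep(NA_real_, length(beta)),
                   wald = rep(NA_real_, length(beta)),
                   p_values = rep(NA_real_, length(beta)),
                   dropped = character(0), fit = NULL,
                   ridge = list(beta = beta, columns = colnames(xm))),
              class = "logistic_model")
  })
}

predict_model_safe <- function(model, newx) {
  if (is.null(model$ridge)) return(predict_logistic(model, newx))
  xm <- as.matrix(newx)[, model$ridge$columns, drop = FALSE]
  as.numeric(plogis(model$ridge$beta[1] +
                      xm %*% model$ridge$beta[-1]))
}

#' Run the full LVSI-prediction pipeline on a synthetic cohort
#'
#' Executes all stages in order: registry generation, eligibility
#' filtering, external-set withdrawal and seeded 7:3 split; per-patient
#' PET simulation, 42% SUVmax segmentation and 401-feature extraction;
#' stain-summary simulation with H-score quantification for TNC and
#' COX-2; Z-score normalisation fitted on the training set; LASSO
#' selection and Rad-score construction; radiomics / protein / combined
#' logistic models with ROC evaluation and pairwise DeLong tests on
#' every split; Mann-Whitney univariate comparisons, Spearman
#' correlations and the all-patient multivariate logistic model; and an
#' optional two-reader ICC sub-study.  Identical configuration and seed
#' give an identical report.
#'
#' @param config a [run_config()].
#' @return list of class `eval_report`; see the fields `cohort`,
#'   `lasso`, `radscore_model`, `models`, `evaluation`, `delong`,
#'   `univariate`, `spearman`, `multivariate`, `icc`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  sim <- config$sim
  sim$seed <- seed

  registry <- generate_registry(sim)
  parts <- apply_eligibility(registry)
  elig <- parts$eligible
  n_ext <- min(config$n_external, max(nrow(elig) - 2L, 0L))
  if (n_ext > 0L) {
    set.seed(derive_seed(seed, 2L))
    ext_idx <- sample.int(nrow(elig), n_ext)
    external <- elig[ext_idx, , drop = FALSE]
    external$split <- "external"
    core <- elig[-ext_idx, , drop = FALSE]
  } else {
    external <- elig[0L, , drop = FALSE]
    core <- elig
  }
  core <- split_cohort(core, config$split_ratio, derive_seed(seed, 1L))
  cohort <- rbind(core, external)

  # image simulation + feature extraction
  feats <- matrix(NA_real_, nrow(cohort), 401L,
                  dimnames = list(cohort$id, feature_catalog()$name))
  case_seed <- function(id) derive_seed(seed, 100L + match(id, registry$id))
  for (i in seq_len(nrow(cohort))) {
    cs <- case_seed(cohort$id[i])
    case <- generate_pet_case(cohort$lvsi[i], sim, cs)
    voi <- segment_voi(case$volume, config$threshold_fraction)
    feats[i, ] <- extract_all(case$volume, voi, config$n_levels)
  }

  # IHC quantification
  ihc_group <- function(protein, stream0) {
    vapply(seq_len(nrow(cohort)), function(i) {
      ss <- generate_stain_summary(
        cohort$lvsi[i], protein, sim,
        derive_seed(seed, stream0 + match(cohort$id[i], registry$id)))
      pos <- positivity(ss)
      h_score(pos$intensity_category, pos$percentage_category)$group
    }, integer(1))
  }
  cohort$tnc_group <- ihc_group("TNC", 10000L)
  cohort$cox2_group <- ihc_group("COX2", 20000L)

  is_train <- cohort$split == "train"
  is_test <- cohort$split == "test"
  is_ext <- cohort$split == "external"
  y <- cohort$lvsi

  zs <- suppressWarnings(
    zscore_fit_apply(feats[is_train, , drop = FALSE],
                     feats[is_test, , drop = FALSE],
                     feats[is_ext, , drop = FALSE]))
  ztab <- matrix(NA_real_, nrow(cohort), ncol(zs$train),
                 dimnames = list(cohort$id, colnames(zs$train)))
  ztab[is_train, ] <- zs$train
  ztab[is_test, ] <- zs$others[[1]]
  ztab[is_ext, ] <- zs$others[[2]]

  sel <- lasso_select(zs$train, y[is_train],
                      lasso_config(seed = derive_seed(seed, 3L)))
  rs_model <- rad_score_model_from_selection(sel)
  radscore <- if (length(rs_model$feature_names))
    rad_score(rs_model, ztab) else rep(rs_model$intercept, nrow(ztab))
  cohort$rad_score <- radscore

  pred_tab <- data.frame(rad_score = radscore,
                         tnc = cohort$tnc_group,
                         cox2 = cohort$cox2_group)
  model_defs <- list(radiomics = "rad_score",
                     protein = c("tnc", "cox2"),
                     combined = c("rad_score", "tnc", "cox2"))
  models <- lapply(model_defs, function(cols)
    fit_model_safe(pred_tab[is_train, cols, drop = FALSE], y[is_train]))

  splits <- list(train = is_train, test = is_test, external = is_ext)
  evaluation <- list()
  delong <- list()
  for (sp in names(splits)) {
    sel_rows <- splits[[sp]]
    if (!any(sel_rows) || length(unique(y[sel_rows])) < 2L) next
    preds <- lapply(names(model_defs), function(mn)
      predict_model_safe(models[[mn]],
                         pred_tab[sel_rows, model_defs[[mn]],
                                  drop = FALSE]))
    names(preds) <- names(model_defs)
    evaluation[[sp]] <- lapply(preds, roc_auc, labels = y[sel_rows])
    prs <- utils::combn(names(preds), 2L)
    delong[[sp]] <- lapply(seq_len(ncol(prs)), function(k)
      c(list(pair = paste(prs[, k], collapse = " vs ")),
        unclass(delong_compare(preds[[prs[1, k]]], preds[[prs[2, k]]],
                               y[sel_rows]))))
  }

  # univariate Mann-Whitney between LVSI groups on all patients
  uni_vars <- list(COX2 = cohort$cox2_group, TNC = cohort$tnc_group,
                   SUVmax = feats[, "SUVmax"], TLG = feats[, "TLG"],
                   SUVpeak = feats[, "SUVpeak"],
                   `Rad-score` = radscore)
  univariate <- do.call(rbind, lapply(names(uni_vars), function(v) {
    mw <- mann_whitney(uni_vars[[v]][y == 1L], uni_vars[[v]][y == 0L])
    data.frame(variable = v, u = mw$u, wilcoxon_w = mw$wilcoxon_w,
               z = mw$z, p = mw$p)
  }))

  spearman_pairs <- list(
    c("LVSI", "Rad-score"), c("LVSI", "TNC"), c("LVSI", "COX2"),
    c("TNC", "Rad-score"), c("TNC", "COX2"))
  sp_vars <- list(LVSI = y, `Rad-score` = radscore,
                  TNC = cohort$tnc_group, COX2 = cohort$cox2_group)
  spearman <- do.call(rbind, lapply(spearman_pairs, function(pr) {
    st <- tryCatch(spearman_test(sp_vars[[pr[1]]], sp_vars[[pr[2]]]),
                   error = function(e) list(rho = NA_real_,
                                            p = NA_real_))
    data.frame(var1 = pr[1], var2 = pr[2], rho = st$rho, p = st$p)
  }))

  multivariate <- fit_model_safe(pred_tab, y)

  icc <- NULL
  n_icc <- min(config$icc_cases, sum(is_train))
  if (n_icc > 0L) {
    icc_ids <- cohort$id[is_train][seq_len(n_icc)]
    r2 <- matrix(NA_real_, n_icc, 401L,
                 dimnames = list(icc_ids, feature_catalog()$name))
    for (i in seq_len(n_icc)) {
      id <- icc_ids[i]
      case <- generate_pet_case(cohort$lvsi[cohort$id == id], sim,
                                case_seed(id))
      voi2 <- segment_voi(case$volume, config$icc_second_fraction)
      r2[i, ] <- extract_all(case$volume, voi2, config$n_levels)
    }
    icc <- suppressWarnings(
      icc_feature_summary(feats[icc_ids, , drop = FALSE], r2))
  }

  report <- structure(list(
    cohort = list(n_total = nrow(registry),
                  n_eligible = nrow(elig),
                  n_excluded = nrow(parts$excluded),
                  n_train = sum(is_train), n_test = sum(is_test),
                  n_external = sum(is_ext)),
    registry = registry,
    patients = cohort,
    features = feats,
    lasso = list(lambda = sel$lambda,
                 n_selected = length(sel$selected),
                 selected = sel$selected,
                 cv_deviance = sel$cv_deviance),
    radscore_model = rs_model,
    normalization = list(center = zs$center, scale = zs$scale,
                         dropped = zs$dropped),
    models = models,
    evaluation = evaluation,
    delong = delong,
    univariate = univariate,
    spearman = spearman,
    multivariate = multivariate,
    icc = icc,
    manifest = list(seed = seed,
                    split_ratio = config$split_ratio,
                    n_external = config$n_external,
                    n_levels = config$n_levels,
                    threshold_fraction = config$threshold_fraction,
                    icc_cases = config$icc_cases)),
    class = "eval_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.eval_report <- function(x, ...) {
  co <- x$cohort
  cat("LVSI pipeline report\n")
  cat(sprintf("  cohort: %d patients, %d eligible (%d excluded); train/test/external = %d/%d/%d\n",
              co$n_total, co$n_eligible, co$n_excluded,
              co$n_train, co$n_test, co$n_external))
  cat(sprintf("  LASSO: lambda = %.4g, %d features selected\n",
              x$lasso$lambda, x$lasso$n_selected))
  for (sp in names(x$evaluation)) {
    cat("  ", sp, "AUCs:",
        paste(sprintf("%s %.3f", names(x$evaluation[[sp]]),
                      vapply(x$evaluation[[sp]], `[[`, 0, "auc")),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Persist an evaluation report
#'
#' Writes the feature table and patient table as CSV and a JSON summary
#' (cohort counts, LASSO selection, per-split evaluation, DeLong,
#' univariate/multivariate tables, ICC count, manifest) to `dir`.  The
#' JSON is byte-identical across runs with the same configuration and
#' seed.
#'
#' @param report an `eval_report`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "eval_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(data.frame(id = rownames(report$features),
                       report$features, check.names = FALSE),
            file.path(dir, "features.csv"), row.names = FALSE)
  write.csv(report$patients, file.path(dir, "patients.csv"),
            row.names = FALSE)
  summarise_model <- function(m)
    list(terms = m$terms, coefficients = m$coefficients,
         standard_errors = m$standard_errors, wald = m$wald,
         p_values = m$p_values)
  js <- list(
    cohort = report$cohort,
    lasso = report$lasso[c("lambda", "n_selected", "selected")],
    radscore_model = unclass(report$radscore_model),
    models = lapply(report$models, summarise_model),
    evaluation = lapply(report$evaluation, function(sp)
      lapply(sp, function(r) unclass(r))),
    delong = report$delong,
    univariate = report$univariate,
    spearman = report$spearman,
    multivariate = summarise_model(report$multivariate),
    icc = if (!is.null(report$icc))
      list(n_above_threshold = report$icc$n_above_threshold,
           threshold = report$icc$threshold),
    manifest = report$manifest)
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
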