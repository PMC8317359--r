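#' Simulation configuration for the synthetic study cohort
#'
#' Defines the study conditions the generators emulate: cohort size and
#' the three exclusion counts, LVSI prevalence (default 0.49, the
#' reported marginal), spherical tumours with high FDG avidity (mean
#' SUV 8 over background 1 so a 42% SUVmax threshold cleanly separates
#' tumour from background), a spatially correlated Gaussian
#' heterogeneity field whose amplitude/correlation length depend on the
#' latent LVSI class (LVSI-positive tumours are more heterogeneous),
#' and LVSI-conditional ordinal expression distributions for TNC and
#' COX-2 calibrated to the reported marginal group frequencies.
#'
#' The LVSI-positive class must be at least as heterogeneous as the
#' negative class (higher `field_sd` or shorter
#' `correlation_length_mm`); equality on both axes is allowed so that
#' null (no-signal) cohorts can be simulated.
#'
#' @param n_patients registry size before eligibility filtering.
#' @param lvsi_prevalence probability of LVSI among patients.
#' @param tumor_radius_mm spherical tumour radius.
#' @param background_suv,tumor_mean_suv SUV of background tissue and
#'   mean tumour SUV.
#' @param tumor_mean_sd between-patient SD of the tumour mean SUV
#'   (biological avidity variation, independent of LVSI).
#' @param voxel_noise_sd SD of uncorrelated voxel-level measurement
#'   noise added to tumour voxels in both classes (reconstruction
#'   noise; sets the floor below which texture contrast is not
#'   recoverable).
#' @param spacing voxel spacing in mm.
#' @param heterogeneity_field list with elements `negative` and
#'   `positive`, each `list(correlation_length_mm=, field_sd=)`.
#' @param protein_effect list per protein (`TNC`, `COX2`) of
#'   LVSI-conditional probabilities over the three expression groups.
#' @param case_jitter multiplicative between-patient variability
#'   (log-normal scale SDs) of the tumour radius, correlation length
#'   and field SD; makes tumours within a class heterogeneous in size
#'   and texture so class contrasts are realistic rather than
#'   deterministic.
#' @param exclusion_counts named counts for `prior_therapy`,
#'   `small_volume`, `external_surgery`.
#' @param clip_margin tumour voxels are clipped to stay at least this
#'   far above the background SUV.
#' @param seed master seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 131L,
                       lvsi_prevalence = 0.49,
                       tumor_radius_mm = 15,
                       background_suv = 1.0,
                       tumor_mean_suv = 8.0,
                       tumor_mean_sd = 1.5,
                       voxel_noise_sd = 0.6,
                       spacing = c(3, 3, 3),
                       heterogeneity_field = list(
                         negative = list(correlation_length_mm = 5,
                                         field_sd = 1.0),
                         positive = list(correlation_length_mm = 3.5,
                                         field_sd = 1.15)),
                       protein_effect = list(
                         TNC = list(negative = c(0.80, 0.16, 0.04),
                                    positive = c(0.50, 0.36, 0.14)),
                         COX2 = list(negative = c(0.58, 0.32, 0.10),
                                     positive = c(0.33, 0.45, 0.22))),
                       case_jitter = list(radius = 0.15,
                                          correlation = 0.25,
                                          sd = 0.2),
                       exclusion_counts = c(prior_therapy = 5L,
                                            small_volume = 10L,
                                            external_surgery = 4L),
                       clip_margin = 0.1,
                       seed = 1L) {
  stopifnot(n_patients >= 1L,
            lvsi_prevalence >= 0, lvsi_prevalence <= 1,
            tumor_radius_mm > 0, background_suv > 0,
            tumor_mean_suv > background_suv, tumor_mean_sd >= 0,
            voxel_noise_sd >= 0,
            all(unlist(case_jitter) >= 0),
            length(spacing) == 3L, all(spacing > 0),
            clip_margin > 0)
  exclusion_counts <- as.integer(exclusion_counts)
  names(exclusion_counts) <- c("prior_therapy", "small_volume",
                               "external_surgery")
  if (any(exclusion_counts < 0))
    stop("exclusion counts must be non-negative")
  if (sum(exclusion_counts) > n_patients)
    stop("exclusion counts exceed the number of patients")
  for (pr in names(protein_effect)) {
    for (cl in c("negative", "positive")) {
      p <- protein_effect[[pr]][[cl]]
      if (length(p) != 3L || any(p < 0) || any(p > 1) ||
          abs(sum(p) - 1) > 1e-8)
        stop("protein_effect$", pr, "$", cl,
             " must be 3 probabilities summing to 1")
    }
  }
  hn <- heterogeneity_field$negative
  hp <- heterogeneity_field$positive
  stopifnot(hn$correlation_length_mm > 0, hp$correlation_length_mm > 0,
            hn$field_sd >= 0, hp$field_sd >= 0)
  if (hp$field_sd < hn$field_sd ||
      hp$correlation_length_mm > hn$correlation_length_mm)
    stop("LVSI-positive class must be at least as heterogeneous as ",
         "the negative class (field_sd and correlation_length_mm)")
  structure(list(n_patients = as.integer(n_patients),
                 lvsi_prevalence = lvsi_prevalence,
                 tumor_radius_mm = tumor_radius_mm,
                 background_suv = background_suv,
                 tumor_mean_suv = tumor_mean_suv,
                 tumor_mean_sd = tumor_mean_sd,
                 voxel_noise_sd = voxel_noise_sd,
                 case_jitter = case_jitter,
                 spacing = as.numeric(spacing),
                 heterogeneity_field = heterogeneity_field,
                 protein_effect = protein_effect,
                 exclusion_counts = exclusion_counts,
                 clip_margin = clip_margin,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @param ... overrides passed on to [sim_config()].
#' @details `null_sim_config()` returns a configuration with no planted
#'   signal: identical heterogeneity in both LVSI classes and protein
#'   expression independent of LVSI, for null-calibration runs.
#' @export
null_sim_config <- function(...) {
  marg <- list(TNC = c(0.66, 0.26, 0.08), COX2 = c(0.45, 0.39, 0.16))
  sim_config(
    heterogeneity_field = list(
      negative = list(correlation_length_mm = 4.2, field_sd = 1.05),
      positive = list(correlation_length_mm = 4.2, field_sd = 1.05)),
    protein_effect = list(
      TNC = list(negative = marg$TNC, positive = marg$TNC),
      COX2 = list(negative = marg$COX2, positive = marg$COX2)),
    ...)
}

#' Generate a synthetic patient registry
#'
#' Draws `n_patients` records with age, FIGO stage, grade, stromal
#' invasion depth, a latent LVSI label at the configured prevalence and
#' LVSI-conditional TNC/COX-2 expression groups; exactly the configured
#' numbers of records carry each exclusion flag (assigned to distinct
#' random patients), the rest are eligible.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `id`, `age`, `figo_stage`, `grade`,
#'   `stromal_invasion`, `lvsi`, `tnc_group`, `cox2_group`,
#'   `exclusion_flags`, `split`.
#' @export
generate_registry <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  set.seed(derive_seed(config$seed, 0L))
  lvsi <- rbinom(n, 1L, config$lvsi_prevalence)
  draw_group <- function(protein) {
    vapply(lvsi, function(l) {
      p <- config$protein_effect[[protein]][[
        if (l == 1L) "positive" else "negative"]]
      sample.int(3L, 1L, prob = p) - 1L
    }, integer(1))
  }
  age <- pmin(pmax(round(rnorm(n, 51, 8)), 33L), 74L)
  figo <- sample(c("Ia", "Ib", "IIa"), n, replace = TRUE,
                 prob = c(0.27, 0.42, 0.31))
  grade <- sample(c("well", "moderate", "poor"), n, replace = TRUE,
                  prob = c(0.23, 0.52, 0.25))
  stromal <- sample(c(">=1/2", "<1/2"), n, replace = TRUE,
                    prob = c(0.73, 0.27))
  flags <- rep("", n)
  ex <- config$exclusion_counts
  if (sum(ex) > 0L) {
    idx <- sample.int(n, sum(ex))
    flags[idx] <- rep(names(ex), times = ex)
  }
  data.frame(id = sprintf("P%03d", seq_len(n)),
             age = age, figo_stage = figo, grade = grade,
             stromal_invasion = stromal, lvsi = lvsi,
             tnc_group = draw_group("TNC"),
             cox2_group = draw_group("COX2"),
             exclusion_flags = flags,
             split = ifelse(nzchar(flags), "excluded", ""),
             stringsAsFactors = FALSE)
}

# Separable Gaussian smoothing of a 3-D array; per-axis sigma in voxels.
# Kernel rows are renormalised at the edges.
gauss_smooth3d <- function(a, sigma) {
  d <- dim(a)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    n <- d[ax]
    k <- exp(-outer(seq_len(n), seq_len(n), `-`)^2 / (2 * s^2))
    k <- k / rowSums(k)
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    ap <- array(k %*% matrix(ap, nrow = n), dim = d[perm])
    a <- aperm(ap, order(perm))
  }
  a
}

#' Generate one synthetic PET case
#'
#' Builds a spherical tumour of the configured radius inside a grid
#' sized to leave a margin, with voxel SUV = tumour mean + a spatially
#' correlated Gaussian field (Gaussian-smoothed white noise, kernel
#' width = the class correlation length, rescaled to the class
#' `field_sd`), clipped to stay strictly above background; the
#' LVSI-positive class is more heterogeneous.  The returned mask marks
#' the ground-truth tumour extent.
#'
#' @param lvsi logical/0-1 LVSI class of the case.
#' @param config a [sim_config()].
#' @param seed integer seed for this case.
#' @param grid_dim optional grid dimensions; the tumour must fit with a
#'   margin of at least 2 voxels, otherwise the case is rejected.
#' @return list with `volume` ([pet_volume()]) and `mask`
#'   ([voi_mask()]).
#' @export
generate_pet_case <- function(lvsi, config, seed, grid_dim = NULL) {
  stopifnot(inherits(config, "sim_config"))
  sp <- config$spacing
  jit <- config$case_jitter
  set.seed(seed)
  case_mean <- max(config$tumor_mean_suv +
                     config$tumor_mean_sd * rnorm(1),
                   config$background_suv + 10 * config$clip_margin)
  r <- config$tumor_radius_mm * exp(rnorm(1, 0, jit$radius))
  pars <- config$heterogeneity_field[[
    if (as.integer(lvsi) == 1L) "positive" else "negative"]]
  corr_len <- pars$correlation_length_mm * exp(rnorm(1, 0, jit$correlation))
  field_sd <- pars$field_sd * exp(rnorm(1, 0, jit$sd))
  if (pars$field_sd == 0) field_sd <- 0
  half_needed <- ceiling(r / sp)
  if (is.null(grid_dim)) {
    grid_dim <- 2L * (half_needed + 4L) + 1L
  } else {
    grid_dim <- as.integer(grid_dim)
    stopifnot(length(grid_dim) == 3L)
    if (any((grid_dim - 1L) %/% 2L < half_needed + 2L))
      stop("tumour does not fit in the grid with a 2-voxel margin")
  }
  ctr <- (grid_dim + 1) / 2
  d2 <- outer(outer(((seq_len(grid_dim[1]) - ctr[1]) * sp[1])^2,
                    ((seq_len(grid_dim[2]) - ctr[2]) * sp[2])^2, `+`),
              ((seq_len(grid_dim[3]) - ctr[3]) * sp[3])^2, `+`)
  mask <- d2 <= r^2
  suv <- array(config$background_suv, grid_dim)
  tum <- rep(case_mean, sum(mask))
  if (field_sd > 0) {
    w <- array(rnorm(prod(grid_dim)), grid_dim)
    f <- gauss_smooth3d(w, corr_len / sp)
    f <- f / sd(f) * field_sd
    tum <- tum + f[mask]
  }
  if (config$voxel_noise_sd > 0)
    tum <- tum + rnorm(length(tum), sd = config$voxel_noise_sd)
  suv[mask] <- pmax(tum, config$background_suv + config$clip_margin)
  list(volume = pet_volume(suv, sp), mask = voi_mask(mask))
}

# (intensity, percentage) category pairs whose H-score falls in each
# printed expression group; group 0 is represented as fully negative
# tissue (see vignette).
hscore_pairs_by_group <- list(
  `0` = matrix(c(0L, 0L), ncol = 2L),
  `1` = matrix(c(1L, 3L, 1L, 4L, 2L, 2L, 2L, 3L, 3L, 1L),
               ncol = 2L, byrow = TRUE),
  `2` = matrix(c(2L, 4L, 3L, 3L, 3L, 4L), ncol = 2L, byrow = TRUE))

pct_band <- list(c(0, 0), c(0.005, 0.045), c(0.055, 0.195),
                 c(0.215, 0.495), c(0.51, 0.95))

#' Generate a synthetic stain-pixel summary
#'
#' Draws an expression group from the LVSI-conditional distribution for
#' the protein, then an (intensity, percentage) category pair
#' consistent with that group's printed H-scores and a positive-area
#' fraction inside the percentage band, and emits pixel counts whose
#' quantification ([positivity()] + [h_score()]) recovers the draw.
#'
#' @param lvsi logical/0-1 LVSI class.
#' @param protein `"TNC"` or `"COX2"`.
#' @param config a [sim_config()].
#' @param seed integer seed for this draw.
#' @param total_pixels tile size in pixels (default 20000).
#' @return a [stain_summary()].
#' @export
generate_stain_summary <- function(lvsi, protein, config, seed,
                                   total_pixels = 20000L) {
  stopifnot(inherits(config, "sim_config"),
            protein %in% names(config$protein_effect))
  p <- config$protein_effect[[protein]][[
    if (as.integer(lvsi) == 1L) "positive" else "negative"]]
  set.seed(seed)
  grp <- sample.int(3L, 1L, prob = p) - 1L
  pairs <- hscore_pairs_by_group[[as.character(grp)]]
  pick <- pairs[sample.int(nrow(pairs), 1L), ]
  intensity <- pick[1]
  pct <- pick[2]
  band <- pct_band[[pct + 1L]]
  frac <- if (pct == 0L) 0 else runif(1, band[1], band[2])
  n_pos <- round(frac * total_pixels)
  counts <- c(strong = 0L, moderate = 0L, weak = 0L)
  if (n_pos > 0L)
    counts[c("weak", "moderate", "strong")[intensity]] <- n_pos
  stain_summary(counts["strong"], counts["moderate"], counts["weak"],
                total_pixels - n_pos)
}
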