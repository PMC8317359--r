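# Monte-Carlo pipeline replicates are expensive; several property tests
# share them, so they are computed once per test run and cached here.
.replicate_cache <- new.env(parent = emptyenv())

# 20 seeded replicates of the full pipeline on a planted-signal cohort
# of 200 eligible patients (no exclusions, no external set).
planted_replicates <- function() {
  if (!is.null(.replicate_cache$planted)) return(.replicate_cache$planted)
  out <- lapply(1:20, function(k) {
    cfg <- run_config(
      sim = sim_config(n_patients = 200L,
                       exclusion_counts = c(0L, 0L, 0L)),
      n_external = 0L, icc_cases = 0L, seed = 1000L + k)
    rep <- suppressWarnings(run_pipeline(cfg))
    comb <- rep$multivariate
    list(test_auc = rep$evaluation$test$radiomics$auc,
         test_auc_combined = rep$evaluation$test$combined$auc,
         comb_sign_rad = comb$coefficients[match("rad_score",
                                                 comb$terms)] > 0,
         comb_sign_tnc = comb$coefficients[match("tnc", comb$terms)] > 0)
  })
  .replicate_cache$planted <- out
  out
}

# 20 seeded replicates of a null cohort (no planted effect), 120
# eligible patients each.
null_replicates <- function() {
  if (!is.null(.replicate_cache$null)) return(.replicate_cache$null)
  out <- lapply(1:20, function(k) {
    cfg <- run_config(
      sim = null_sim_config(n_patients = 120L,
                            exclusion_counts = c(0L, 0L, 0L)),
      n_external = 0L, icc_cases = 0L, seed = 3000L + k)
    rep <- suppressWarnings(run_pipeline(cfg))
    list(test_auc = rep$evaluation$test$combined$auc)
  })
  .replicate_cache$null <- out
  out
}

# tiny deterministic PET case for feature-level tests
tiny_case <- function(seed = 5L, lvsi = 1L) {
  sc <- sim_config()
  case <- generate_pet_case(lvsi, sc, seed)
  voi <- segment_voi(case$volume)
  list(volume = case$volume, voi = voi)
}
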