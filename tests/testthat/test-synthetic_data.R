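test_that("registry generation honours exclusion counts and prevalence", {
  sc <- sim_config(n_patients = 131L, seed = 4L)
  reg <- generate_registry(sc)
  expect_equal(nrow(reg), 131L)
  expect_equal(sum(reg$exclusion_flags == "prior_therapy"), 5L)
  expect_equal(sum(reg$exclusion_flags == "small_volume"), 10L)
  expect_equal(sum(reg$exclusion_flags == "external_surgery"), 4L)
  expect_equal(sum(!nzchar(reg$exclusion_flags)), 112L)

  reg2 <- generate_registry(sim_config(n_patients = 10L,
                                       exclusion_counts = c(0L, 0L, 0L)))
  expect_equal(sum(!nzchar(reg2$exclusion_flags)), 10L)

  sc3 <- sim_config(n_patients = 50L, exclusion_counts = c(5L, 5L, 5L),
                    seed = 9L)
  expect_identical(generate_registry(sc3), generate_registry(sc3))

  expect_error(sim_config(n_patients = 10L,
                          exclusion_counts = c(5L, 5L, 5L)),
               "exceed")
  expect_error(sim_config(exclusion_counts = c(-1L, 0L, 0L)),
               "non-negative")
})

test_that("config validation enforces probabilities and heterogeneity order", {
  expect_error(sim_config(lvsi_prevalence = 1.2))
  expect_error(sim_config(protein_effect = list(
    TNC = list(negative = c(0.5, 0.4, 0.2), positive = c(0.5, 0.4, 0.1)),
    COX2 = list(negative = c(1, 0, 0), positive = c(1, 0, 0)))),
    "summing to 1")
  # positive class less heterogeneous than negative is rejected
  expect_error(sim_config(heterogeneity_field = list(
    negative = list(correlation_length_mm = 3, field_sd = 1.5),
    positive = list(correlation_length_mm = 6, field_sd = 1.0))),
    "heterogeneous")
  # equality allowed (null simulations)
  expect_s3_class(null_sim_config(), "sim_config")
})

test_that("PET case generator: zero-noise limit, determinism, fit check", {
  quiet <- sim_config(
    tumor_mean_sd = 0, voxel_noise_sd = 0,
    case_jitter = list(radius = 0, correlation = 0, sd = 0),
    heterogeneity_field = list(
      negative = list(correlation_length_mm = 5, field_sd = 0),
      positive = list(correlation_length_mm = 5, field_sd = 0)))
  case <- generate_pet_case(1, quiet, seed = 3L)
  tum <- case$volume$suv[case$mask$mask]
  expect_true(all(tum == quiet$tumor_mean_suv))
  expect_true(all(case$volume$suv[!case$mask$mask] ==
                    quiet$background_suv))

  sc <- sim_config()
  a <- generate_pet_case(1, sc, seed = 77L)
  b <- generate_pet_case(1, sc, seed = 77L)
  expect_identical(a$volume$suv, b$volume$suv)
  expect_identical(a$mask$mask, b$mask$mask)

  expect_error(generate_pet_case(1, sc, 1L, grid_dim = c(5L, 5L, 5L)),
               "does not fit")
})

test_that("within-tumour SUV variance is larger in the LVSI-positive class", {
  sc <- sim_config()
  n <- 250
  vpos <- vneg <- numeric(n)
  for (i in seq_len(n)) {
    a <- generate_pet_case(1, sc, 50000L + i)
    b <- generate_pet_case(0, sc, 60000L + i)
    vpos[i] <- var(a$volume$suv[a$mask$mask])
    vneg[i] <- var(b$volume$suv[b$mask$mask])
  }
  expect_gt(mean(vpos), mean(vneg))
})

test_that("stain summaries follow the LVSI-conditional expression model", {
  sc <- sim_config()
  # degenerate on group 0 -> fully negative tissue
  degen <- sim_config(protein_effect = list(
    TNC = list(negative = c(1, 0, 0), positive = c(1, 0, 0)),
    COX2 = list(negative = c(1, 0, 0), positive = c(1, 0, 0))))
  ss <- generate_stain_summary(1, "TNC", degen, seed = 2L)
  expect_equal(ss$n_strong + ss$n_moderate + ss$n_weak, 0)
  expect_equal(positivity(ss)$positive_fraction, 0)

  # determinism
  expect_identical(generate_stain_summary(1, "TNC", sc, 11L),
                   generate_stain_summary(1, "TNC", sc, 11L))

  # Monte-Carlo sign check: TNC group positively associated with LVSI
  grp <- function(lvsi, i) {
    s <- generate_stain_summary(lvsi, "TNC", sc, 70000L + i)
    p <- positivity(s)
    h_score(p$intensity_category, p$percentage_category)$group
  }
  g1 <- vapply(1:500, function(i) grp(1, i), integer(1))
  g0 <- vapply(1:500, function(i) grp(0, 1000L + i), integer(1))
  st <- spearman_test(c(rep(1, 500), rep(0, 500)), c(g1, g0))
  expect_gt(st$rho, 0)
  expect_lt(st$p, 0.01)
})
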