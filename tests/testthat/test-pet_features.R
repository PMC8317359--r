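test_that("fixed-threshold segmentation keeps the hottest component", {
  # uniform volume: every voxel above 42% of max
  v <- pet_volume(array(10, c(3, 3, 3)), c(1, 1, 1))
  expect_true(all(segment_voi(v)$mask))

  # 1-D profile [1,5,10,5,1]: threshold 4.2 keeps {5,10,5}
  v2 <- pet_volume(array(c(1, 5, 10, 5, 1), c(5, 1, 1)), c(1, 1, 1))
  expect_equal(as.vector(segment_voi(v2)$mask),
               c(FALSE, TRUE, TRUE, TRUE, FALSE))

  # two disjoint hot blobs: only the one containing the max is kept
  a <- array(1, c(9, 3, 3))
  a[1:2, 2, 2] <- 8     # blob A with the global max
  a[8:9, 2, 2] <- 7     # blob B, above threshold but disconnected
  v3 <- pet_volume(a, c(1, 1, 1))
  m3 <- segment_voi(v3)$mask
  expect_true(all(m3[1:2, 2, 2]))
  expect_false(any(m3[8:9, , ]))

  expect_error(segment_voi(pet_volume(array(0, c(2, 2, 2)) + 0,
                                      c(1, 1, 1))),
               "no positive uptake")
})

test_that("conventional metrics: hand arithmetic and invariants", {
  # single voxel, SUV 10, voxel volume 1 cm^3
  v <- pet_volume(array(10, c(1, 1, 1)), c(10, 10, 10))
  m <- voi_mask(array(TRUE, c(1, 1, 1)))
  cm <- conventional_metrics(v, m)
  expect_equal(unname(cm[c("MTV", "TLG", "SUVmax", "SUVmean")]),
               c(1, 10, 10, 10))

  # two voxels {4, 8} at 0.5 cm^3 each
  v2 <- pet_volume(array(c(4, 8), c(2, 1, 1)),
                   c(10, 10, 5))
  m2 <- voi_mask(array(TRUE, c(2, 1, 1)))
  cm2 <- conventional_metrics(v2, m2)
  expect_equal(unname(cm2["SUVmean"]), 6)
  expect_equal(unname(cm2["MTV"]), 1.0)
  expect_equal(unname(cm2["TLG"]), 6.0)

  # uniform tumour: peak equals max; TLG identity holds generally
  v3 <- pet_volume(array(5, c(8, 8, 8)), c(3, 3, 3))
  m3 <- voi_mask(array(TRUE, c(8, 8, 8)))
  cm3 <- conventional_metrics(v3, m3)
  expect_equal(unname(cm3["SUVpeak"]), unname(cm3["SUVmax"]))
  expect_lte(cm3["SUVmean"], cm3["SUVmax"])
  expect_equal(unname(cm3["TLG"]), unname(cm3["SUVmean"] * cm3["MTV"]),
               tolerance = 1e-9)

  expect_error(conventional_metrics(v3, voi_mask(array(FALSE, c(8, 8, 8)))),
               "empty")
})

test_that("quantization bins the in-mask range into equal widths", {
  m <- voi_mask(array(TRUE, c(2, 1, 1)))
  # constant region -> all level 1
  vq <- quantize_voi(pet_volume(array(3, c(2, 1, 1)), c(1, 1, 1)), m, 64)
  expect_true(all(vq$levels == 1L))
  # {0, 10} with 2 levels -> {1, 2}
  vq2 <- quantize_voi(pet_volume(array(c(0, 10), c(2, 1, 1)),
                                 c(1, 1, 1)), m, 2)
  expect_equal(as.vector(vq2$levels), c(1L, 2L))
  # integers 0..63 with 64 levels -> level i+1
  v64 <- pet_volume(array(0:63, c(64, 1, 1)), c(1, 1, 1))
  m64 <- voi_mask(array(TRUE, c(64, 1, 1)))
  vq3 <- quantize_voi(v64, m64, 64)
  expect_equal(as.vector(vq3$levels), 1:64)
})

test_that("co-occurrence features match the hand-computed 2x2 example", {
  q <- quantized_voi(matrix(c(1L, 1L, 1L, 2L), 2, 2, byrow = TRUE), 2)
  f <- glcm_features(q, 0, 1)
  expect_equal(unname(f["GLCMEnergy"]), 0.375)
  expect_equal(unname(f["Inertia"]), 0.5)
  expect_equal(unname(f["InverseDifferenceMoment"]), 0.75)
  p <- radlvsi:::glcm_matrix(q, 0, 1)
  expect_equal(p, matrix(c(0.5, 0.25, 0.25, 0), 2, 2), tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-9)

  # constant region: single co-occurrence cell
  qc <- quantized_voi(matrix(1L, 3, 3), 1)
  fc <- suppressWarnings(glcm_features(qc, 0, 1))
  expect_equal(unname(fc["GLCMEnergy"]), 1)
  expect_equal(unname(fc["Inertia"]), 0)
  expect_equal(unname(fc["InverseDifferenceMoment"]), 1)

  # no pair at this offset -> zeros with a warning
  expect_warning(f7 <- glcm_features(qc, 0, 7), "no voxel pair")
  expect_true(all(f7 == 0))
})

test_that("90-degree rotation permutes the angle pairs", {
  set.seed(8)
  m <- matrix(sample.int(4, 36, replace = TRUE), 6, 6)
  q <- quantized_voi(m, 4)
  # rotate the slice by 90 degrees
  qr <- quantized_voi(t(m)[ncol(m):1, ], 4)
  for (off in c(1L, 2L)) {
    expect_equal(glcm_features(q, 0, off), glcm_features(qr, 90, off),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(glcm_features(q, 45, off), glcm_features(qr, 135, off),
                 tolerance = 1e-9, ignore_attr = TRUE)
    # AllDirection mean and SD are rotation-invariant
    per_angle <- function(qq) t(sapply(c(0, 45, 90, 135),
                                       function(a) glcm_features(qq, a, off)))
    a1 <- per_angle(q)
    a2 <- per_angle(qr)
    expect_equal(colMeans(a1), colMeans(a2), tolerance = 1e-9)
    expect_equal(apply(a1, 2, function(v) sqrt(mean((v - mean(v))^2))),
                 apply(a2, 2, function(v) sqrt(mean((v - mean(v))^2))),
                 tolerance = 1e-9)
  }
})

test_that("run-length features match hand enumeration", {
  # row [1,1,2]: runs {(1,2),(2,1)}
  q <- quantized_voi(array(c(1L, 1L, 2L), c(1, 3, 1)), 2)
  f <- glrlm_features(q, 0)
  expect_equal(unname(f["ShortRunEmphasis"]), 0.625)
  expect_equal(unname(f["LongRunEmphasis"]), 2.5)

  # constant row of length L: a single run, LRE = L^2
  for (L in c(4L, 7L)) {
    qc <- quantized_voi(array(1L, c(1, L, 1)), 1)
    expect_equal(unname(glrlm_features(qc, 0)["LongRunEmphasis"]),
                 as.numeric(L^2))
  }

  # checkerboard: all axial runs have length 1 (diagonals of a
  # checkerboard are constant, so only angles 0/90 apply)
  chk <- matrix(rep(c(1L, 2L), 8), 4, 4)
  chk[, c(2, 4)] <- 3L - chk[, c(2, 4)]
  qk <- quantized_voi(chk, 2)
  for (a in c(0, 90))
    expect_equal(unname(glrlm_features(qk, a)["ShortRunEmphasis"]), 1)
})

test_that("zone-size features match hand enumeration and scale law", {
  # [[1,1],[2,3]]: zones {(1,2),(2,1),(3,1)}
  q <- quantized_voi(matrix(c(1L, 1L, 2L, 3L), 2, 2, byrow = TRUE), 3)
  f <- glzsm_features(q)
  expect_equal(unname(f["HighIntensityLargeAreaEmphasis"]), 17 / 3)

  # constant region of V voxels: single zone, LowIntensityEmphasis = 1
  qc <- quantized_voi(array(1L, c(3, 4, 1)), 1)
  fc <- glzsm_features(qc)
  expect_equal(unname(fc["LowIntensityEmphasis"]), 1)
  expect_equal(unname(fc["ZoneMax"]), 12)

  # doubling all grey levels scales LowIntensityEmphasis by 1/4
  set.seed(31)
  m <- matrix(sample.int(3, 25, replace = TRUE), 5, 5)
  f1 <- glzsm_features(quantized_voi(m, 3))
  f2 <- glzsm_features(quantized_voi(m * 2L, 6))
  expect_equal(unname(f2["LowIntensityEmphasis"]),
               unname(f1["LowIntensityEmphasis"]) / 4, tolerance = 1e-12)
})

test_that("histogram features: degenerate, quantile and shift behaviour", {
  m <- voi_mask(array(TRUE, c(10, 1, 1)))
  vc <- pet_volume(array(7, c(10, 1, 1)), c(1, 1, 1))
  expect_warning(fc <- histogram_features(vc, m), "zero-variance")
  expect_equal(unname(fc[c("Mean", "Median", "Quantile0.025", "Mode")]),
               rep(7, 4))
  expect_equal(unname(fc[c("Variance", "Skewness", "Kurtosis")]),
               rep(0, 3))

  v100 <- pet_volume(array(1:100, c(100, 1, 1)), c(1, 1, 1))
  m100 <- voi_mask(array(TRUE, c(100, 1, 1)))
  f100 <- histogram_features(v100, m100)
  expect_equal(unname(f100["Quantile0.025"]), 3.475)

  set.seed(12)
  x <- runif(50, 2, 9)
  va <- pet_volume(array(x, c(50, 1, 1)), c(1, 1, 1))
  vb <- pet_volume(array(x + 3, c(50, 1, 1)), c(1, 1, 1))
  ma <- voi_mask(array(TRUE, c(50, 1, 1)))
  fa <- histogram_features(va, ma)
  fb <- histogram_features(vb, ma)
  expect_equal(unname(fb["Mean"]), unname(fa["Mean"]) + 3)
  expect_equal(unname(fb["Variance"]), unname(fa["Variance"]),
               tolerance = 1e-12)
})

test_that("form factors: unit cube, bar and the digital-ball limit", {
  m1 <- voi_mask(array(TRUE, c(1, 1, 1)))
  f1 <- form_factor_features(m1, c(1, 1, 1))
  expect_equal(unname(f1["Volume"]), 1)
  expect_equal(unname(f1["SurfaceArea"]), 6)

  bar <- array(FALSE, c(4, 3, 3))
  bar[2:3, 2, 2] <- TRUE
  f2 <- form_factor_features(voi_mask(bar), c(1, 1, 1))
  expect_equal(unname(f2["SurfaceArea"]), 10)
  expect_equal(unname(f2["Volume"]), 2)

  # face-counting surface of a digital ball tends to 1.5x the smooth
  # sphere, so sphericity tends to 2/3 from around it
  sph <- numeric(0)
  for (r in c(5, 10, 20)) {
    n <- 2L * r + 3L
    ctr <- (n + 1) / 2
    d2 <- outer(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`),
                (seq_len(n) - ctr)^2, `+`)
    f <- form_factor_features(voi_mask(d2 <= r^2), c(1, 1, 1))
    sph <- c(sph, f["Sphericity"])
  }
  expect_lt(abs(sph[3] - 2 / 3), 0.05)
  expect_true(all(sph < 1))
})

test_that("extract_all yields the complete ordered 401-feature vector", {
  case <- tiny_case(seed = 6L)
  fv <- extract_all(case$volume, case$voi)
  expect_length(fv, 401L)
  expect_false(anyNA(fv))
  expect_identical(names(fv), feature_catalog()$name)
  # deterministic
  expect_identical(fv, extract_all(case$volume, case$voi))
  # every published Rad-score feature is present
  expect_true(all(published_radscore_model()$feature_names %in% names(fv)))

  # constant tumour (cube wide enough for offset-7 diagonals):
  # co-occurrence energies 1 at every angle/offset and zero spread
  # across directions for the whole co-occurrence family
  a <- array(1, c(14, 14, 14))
  a[3:12, 3:12, 3:12] <- 8
  vc <- pet_volume(a, c(2, 2, 2))
  mc <- segment_voi(vc)
  fvc <- suppressWarnings(extract_all(vc, mc))
  en <- fvc[grep("^GLCMEnergy_(angle|AllDirection_offset[147]$)",
                 names(fvc))]
  expect_true(all(en == 1))
  glcm_sds <- fvc[grep(
    "^(GLCMEnergy|GLCMEntropy|Inertia|Correlation|InverseDifferenceMoment|ClusterShade|ClusterProminence|HaralickCorrelation)_AllDirection_offset[147]_SD$",
    names(fvc))]
  expect_length(glcm_sds, 24L)
  expect_true(all(glcm_sds == 0))
})

test_that("NIfTI round-trips preserve the grid and spacing", {
  case <- tiny_case(seed = 9L)
  tmp <- tempfile(fileext = ".nii.gz")
  write_pet_volume(case$volume, tmp)
  back <- read_pet_volume(tmp)
  expect_equal(back$suv, case$volume$suv, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$spacing, case$volume$spacing)
  tmp2 <- tempfile(fileext = ".nii.gz")
  write_voi_mask(case$voi, tmp2, case$volume$spacing)
  expect_equal(read_voi_mask(tmp2)$mask, case$voi$mask,
               ignore_attr = TRUE)
  unlink(c(tmp, tmp2))
})
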