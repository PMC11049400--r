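test_that("fixed-bin-width discretization anchors at the ROI minimum", {
  expect_equal(discretize(c(0, 24.9, 25, 60), 25), c(1L, 1L, 2L, 3L))
  expect_equal(discretize(rep(7, 5), 25), rep(1L, 5))
  expect_equal(discretize(c(3, 9), 100), c(1L, 1L))
  expect_error(discretize(1:3, 0), "bin_width")
})

test_that("first-order features match hand computations", {
  f <- first_order_features(c(1, 2, 3), bin_width = 1, shift = 0)
  expect_equal(unname(f["Mean"]), 2)
  expect_equal(unname(f["Range"]), 2)
  expect_equal(unname(f["Median"]), 2)

  f2 <- first_order_features(c(1, 2), bin_width = 1, shift = 0,
                             voxel_volume = 3)
  expect_equal(unname(f2["Energy"]), 5)            # 1^2 + 2^2
  expect_equal(unname(f2["TotalEnergy"]), 15)
  expect_equal(unname(f2["RootMeanSquared"]), sqrt(2.5))

  # two equal-count gray levels: entropy 1 bit, uniformity 0.5
  f3 <- first_order_features(c(0, 0, 30, 30), bin_width = 25, shift = 0)
  expect_equal(unname(f3["Entropy"]), 1)
  expect_equal(unname(f3["Uniformity"]), 0.5)

  # shift enters only the energy family
  f4a <- first_order_features(c(1, 2), bin_width = 1, shift = 1000)
  expect_equal(unname(f4a["Energy"]), 1001^2 + 1002^2)
  expect_equal(unname(f4a["Mean"]), 1.5)

  # degenerate input flags skewness/kurtosis
  f5 <- first_order_features(rep(4, 6), bin_width = 1)
  expect_equal(unname(f5[c("Skewness", "Kurtosis")]), c(0, 0))
  expect_true(all(c("Skewness", "Kurtosis") %in% attr(f5, "flagged")))
})

test_that("first-order location features are order-invariant", {
  set.seed(1)
  x <- rnorm(100, 50, 12)
  a <- first_order_features(x, 25, 1000)
  b <- first_order_features(sample(x), 25, 1000)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("LoG filter response has the expected structure", {
  const <- image_volume(array(100, c(12, 12, 12)))
  r <- log_filter(const, 2)
  expect_lt(max(abs(r$voxels)), 1e-6 * 100)

  # bright Gaussian blob: negative LoG response at the center
  g <- seq(-5, 5)
  blob <- exp(-outer(outer(g^2, g^2, "+"), g^2, "+") / (2 * 2^2))
  vol <- image_volume(array(blob, c(11, 11, 11)))
  resp <- log_filter(vol, 2)
  expect_lt(resp$voxels[6, 6, 6], 0)

  # sigma in mm converts through spacing: same physical blob sampled at
  # doubled spacing gives half the sigma in voxels, so kernels shrink
  expect_error(log_filter(vol, 0), "sigma > 0")
})

test_that("wavelet decomposition yields 8 labelled, energy-preserving bands", {
  set.seed(2)
  arr <- array(rnorm(512), c(8, 8, 8))
  coefs <- dwt3(arr)
  expect_named(coefs, c("LLL", "LLH", "LHL", "LHH",
                        "HLL", "HLH", "HHL", "HHH"))
  expect_true(all(vapply(coefs, function(x) all(dim(x) == 4), logical(1))))
  # Parseval: orthonormal periodized filter bank conserves energy
  expect_equal(sum(arr^2), sum(vapply(coefs, function(x) sum(x^2), numeric(1))),
               tolerance = 1e-10)

  # constant input: all high-pass bands vanish
  coefs2 <- dwt3(array(5, c(8, 8, 8)))
  for (nm in setdiff(names(coefs2), "LLL"))
    expect_lt(max(abs(coefs2[[nm]])), 1e-10)

  # sub-band images keep the input grid size
  vol <- image_volume(array(rnorm(1000), c(10, 10, 10)))
  wb <- wavelet_subbands(vol)
  expect_length(wb, 8)
  expect_true(all(vapply(wb, function(v) all(dim(v$voxels) == 10), logical(1))))
})

test_that("stationary wavelet sub-bands are shift-equivariant in the interior", {
  # translating the input translates every sub-band identically wherever
  # the filter window stays clear of the (mirrored) boundary, so ROI
  # statistics cannot depend on grid alignment
  set.seed(9)
  n <- 12
  arr <- array(rnorm(n * 8 * 8), c(n, 8, 8))
  sh <- array(0, dim = dim(arr))
  sh[4:n, , ] <- arr[1:(n - 3), , ]       # shift by +3 along axis 1
  sh[1:3, , ] <- arr[(n - 2):n, , ]       # filler, excluded from comparison
  w1 <- wavelet_subbands(image_volume(arr))
  w2 <- wavelet_subbands(image_volume(sh))
  rows <- 4:7                              # windows interior in both arrays
  for (nm in names(w1))
    expect_equal(w2[[nm]]$voxels[rows + 3, , ], w1[[nm]]$voxels[rows, , ],
                 tolerance = 1e-12)
})

test_that("preprocessing resamples, normalizes and crops as configured", {
  cfg <- extraction_config("CT")
  dims <- c(16, 16, 16)
  vox <- array(rnorm(prod(dims), 100, 10), dims)
  vol <- image_volume(vox, spacing = c(1, 1, 1))
  mvox <- array(FALSE, dims); mvox[6:10, 6:10, 6:10] <- TRUE
  mask <- roi_mask(mvox, "tumor")

  # already at target spacing: voxels unchanged inside the mask
  pp <- preprocess(vol, mask, cfg)
  expect_equal(pp$volume$voxels[pp$mask$voxels], vox[mvox])

  # 2 mm -> 1 mm: foreground physical volume conserved within 10%
  vol2 <- image_volume(vox, spacing = c(2, 2, 2))
  sph <- sphere_mask <- array(FALSE, dims)
  ctr <- 8.5
  for (i in 1:16) for (j in 1:16) for (k in 1:16)
    sph[i, j, k] <- (i - ctr)^2 + (j - ctr)^2 + (k - ctr)^2 <= 5^2
  mask2 <- roi_mask(sph, "tumor", spacing = c(2, 2, 2))
  pp2 <- preprocess(vol2, mask2, cfg)
  expect_equal(pp2$volume$spacing, c(1, 1, 1))
  v_before <- sum(sph) * 8       # 2mm voxels
  v_after <- sum(pp2$mask$voxels) * 1
  expect_lt(abs(v_after - v_before) / v_before, 0.10)

  # MR path: constant image cannot be normalized
  cfgmr <- extraction_config("MR")
  cvol <- image_volume(array(7, dims), spacing = c(2, 2, 2))
  expect_error(preprocess(cvol, mask2, cfgmr), "zero-variance")
})

test_that("feature vectors have the preset-determined length and order", {
  spec <- phantom_spec(grid_shape = c(16, 16, 16), n_scans = 10)
  p <- generate_patient(spec, 1)
  vol <- p$series$volumes[[8]]

  ct <- extract_all(vol, p$masks$tumor, extraction_config("CT"))
  expect_length(ct, 1204)           # 14 image sets x 86
  expect_equal(sum(grepl("^original_", names(ct))), 86)
  expect_equal(sum(grepl("^wavelet-", names(ct))), 8 * 86)
  expect_equal(sum(grepl("^log-sigma", names(ct))), 5 * 86)

  mr_cfg <- extraction_config("MR")
  mr_cfg$resampled_spacing <- c(1, 1, 1)  # keep the 16^3 grid workable
  mr <- extract_all(vol, p$masks$tumor, mr_cfg)
  expect_length(mr, 1118)           # 13 image sets x 86

  # determinism: identical input, identical vector
  ct2 <- extract_all(vol, p$masks$tumor, extraction_config("CT"))
  expect_identical(ct, ct2)
})
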