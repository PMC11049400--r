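test_that("gamma-variate AIF matches its closed form", {
  # peak value is exactly A at t0 + alpha*beta
  expect_equal(gamma_variate_aif(10 + 3 * 4, t0 = 10, A = 600,
                                 alpha = 3, beta = 4), 600)
  # zero before and at arrival
  expect_equal(gamma_variate_aif(c(0, 5, 10), 10, 600, 3, 4), c(0, 0, 0))
  # direct evaluation of the closed form at t = 14
  expect_equal(gamma_variate_aif(14, 10, 600, 3, 4),
               600 * (4 / 12)^3 * exp(3 - 1))
  expect_error(gamma_variate_aif(1, 0, 1, alpha = -1, beta = 2), "positive")
})

test_that("tissue curve quadrature agrees with the analytic convolution", {
  # constant aif == 1 from t = 0: curve = (k_in/k_out) (1 - exp(-k_out t))
  k_in <- 0.01; k_out <- 0.05
  tt <- c(5, 20, 60)
  got <- tissue_curve(function(t) rep(1, length(t)), 0, k_in, k_out, tt,
                      dt_quad = 0.01)
  expect_equal(got, (k_in / k_out) * (1 - exp(-k_out * tt)), tolerance = 1e-4)
  # no uptake -> flat baseline
  expect_equal(tissue_curve(function(t) rep(1, length(t)), 42, 0, 0.1, tt),
               rep(42, 3))
  # steady state approaches k_in/k_out
  late <- tissue_curve(function(t) rep(1, length(t)), 0, k_in, k_out, 2000,
                       dt_quad = 0.5)
  expect_equal(late, k_in / k_out, tolerance = 1e-3)
  expect_error(tissue_curve(identity, 0, -0.1, 0.1, tt), ">= 0")
})

test_that("scan timing follows the acquisition rule", {
  tt <- scan_times(26)
  expect_equal(diff(tt)[1:19], rep(1.5, 19))
  expect_equal(diff(tt)[20:25], rep(3, 6))
  expect_equal(scan_times(5, "MR", dt = 4.22), 4.22 * (0:4))
})

test_that("patient generation is deterministic and honors the spec", {
  spec <- phantom_spec(n_scans = 12, grid_shape = c(16, 16, 16),
                      texture_length = 2)
  p1 <- generate_patient(spec, 5)
  p2 <- generate_patient(spec, 5)
  expect_identical(p1$series$volumes[[3]]$voxels, p2$series$volumes[[3]]$voxels)
  expect_identical(p1$ground_truth, p2$ground_truth)
  # masks disjoint
  expect_false(any(p1$masks$tumor$voxels & p1$masks$healthy$voxels))
  expect_false(any(p1$masks$tumor$voxels & p1$masks$vessel$voxels))
})

test_that("zero-noise, zero-texture patients reproduce ground truth exactly", {
  spec <- phantom_spec(n_scans = 12, grid_shape = c(16, 16, 16),
                      noise_sd = 0, texture_amp = 0, texture_enh_frac = 0)
  p <- generate_patient(spec, 3)
  tm <- p$masks$tumor$voxels
  for (s in c(1, 6, 12)) {
    vox <- p$series$volumes[[s]]$voxels[tm]
    expect_equal(vox, rep(p$ground_truth$curves$tumor[s], sum(tm)))
  }
  # median vessel curve peaks at the analytic AIF peak scan
  curve <- median_enhancement_curve(p$series, p$masks$vessel)
  expect_equal(which.max(curve$values), p$ground_truth$peak_scan)
})

test_that("cohort peak jitter stays within the stated arterial ranges", {
  spec <- phantom_spec(grid_shape = c(16, 16, 16), n_patients = 10, seed = 11)
  patients <- generate_cohort(spec)
  peaks <- vapply(patients, function(p) {
    curve <- median_enhancement_curve(p$series, p$masks$vessel)
    curve$times[which.max(curve$values)]
  }, numeric(1))
  vals <- vapply(patients, function(p) {
    max(median_enhancement_curve(p$series, p$masks$vessel)$values)
  }, numeric(1))
  # observed peaks within the drawn ranges up to scan-grid + noise slack
  expect_true(all(peaks >= 15 - 3 & peaks <= 26 + 3))
  expect_true(all(vals >= 520 - 30 & vals <= 827 + 30))
  # arrival times genuinely differ across patients
  t0s <- vapply(patients, function(p) p$ground_truth$t0, numeric(1))
  expect_gt(length(unique(round(t0s, 3))), 5)
})

test_that("cohort generation is reproducible and writes a manifest", {
  spec <- phantom_spec(grid_shape = c(12, 12, 12), n_scans = 10,
                      n_patients = 3, seed = 4)
  d <- withr::local_tempdir()
  c1 <- generate_cohort(spec, outdir = d)
  m1 <- attr(c1, "manifest")
  expect_equal(nrow(m1), 3)
  expect_true(all(file.exists(file.path(d, m1$id, "mask_tumor.nrrd"))))
  c2 <- generate_cohort(spec)
  expect_equal(m1$t_peak, attr(c2, "manifest")$t_peak)
  # NRRD round trip of a generated scan
  back <- read_volume(file.path(d, "P001", "scan_01.nrrd"))
  expect_equal(back$voxels, c1[[1]]$series$volumes[[1]]$voxels,
               tolerance = 1e-15)
})
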