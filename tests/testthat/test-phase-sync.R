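piecewise_curve <- function() {
  # 21 scans at 1 s spacing: linear rise 100 -> 200 at scan 11 (1-based),
  # then symmetric fall back to 100
  v <- c(seq(100, 200, by = 10), seq(190, 100, by = -10))
  enhancement_curve(0:20, v)
}

test_that("median enhancement curve takes the per-scan vessel median", {
  dims <- c(4, 4, 4)
  mk_vol <- function(vals) {
    a <- array(0, dims); a[1:length(vals)] <- vals; image_volume(a)
  }
  mvox <- array(FALSE, dims)

  # odd count: median of {90, 100, 110} = 100
  mvox[1:3] <- TRUE
  series <- dynamic_series(replicate(7, mk_vol(c(90, 100, 110)),
                                     simplify = FALSE), 1:7, "CT")
  curve <- median_enhancement_curve(series, roi_mask(mvox, "vessel"))
  expect_equal(curve$values, rep(100, 7))

  # even count: mean of the middle pair {100, 110} = 105
  mvox2 <- array(FALSE, dims); mvox2[1:4] <- TRUE
  series2 <- dynamic_series(replicate(7, mk_vol(c(90, 100, 110, 120)),
                                      simplify = FALSE), 1:7, "CT")
  curve2 <- median_enhancement_curve(series2, roi_mask(mvox2, "vessel"))
  expect_equal(curve2$values, rep(105, 7))

  # constant vessel -> constant curve
  series3 <- dynamic_series(replicate(7, mk_vol(rep(100, 3)),
                                      simplify = FALSE), 1:7, "CT")
  expect_equal(median_enhancement_curve(series3, roi_mask(mvox, "vessel"))$values,
               rep(100, 7))
})

test_that("phase definition reproduces the hand-traced example", {
  a <- define_phases(piecewise_curve())
  # threshold 1.15 * mean(100, 110) = 120.75; midpoints on the time axis
  # (scan 1 = time 0): TP indices here are 1-based scan numbers
  expect_equal(a$tp, c(1, 3, 6, 10, 13, 17, 19) + 1L)
  expect_equal(a$times, c(1, 3, 6, 10, 13, 17, 19))
  expect_equal(length(a$tp), 7)
})

test_that("degenerate curves raise the documented errors", {
  flat <- enhancement_curve(0:9, rep(100, 10))
  expect_error(define_phases(flat), "no bolus detected")
  rising <- enhancement_curve(0:9, seq(100, 280, by = 20))
  expect_error(define_phases(rising), "no washout detected")
})

test_that("phases are scale-invariant but not offset-invariant", {
  base <- define_phases(piecewise_curve())$tp
  scaled <- piecewise_curve(); scaled$values <- scaled$values * 7.3
  expect_equal(define_phases(scaled)$tp, base)
  # a large additive offset shrinks the relative rise: TP2/TP6 move inward
  shifted <- piecewise_curve(); shifted$values <- shifted$values + 1000
  expect_error(define_phases(shifted), "no bolus detected")
})

test_that("phase volumes select (and may repeat) scans by index", {
  vols <- lapply(1:21, function(i) image_volume(array(i, c(2, 2, 2))))
  series <- dynamic_series(vols, 0:20, "CT")
  a <- define_phases(piecewise_curve())
  pv <- phase_volumes(series, a)
  expect_named(pv, paste0("TP", 1:7))
  expect_equal(pv$TP1$voxels[1], 2)  # second acquired scan
  expect_equal(pv$TP4$voxels[1], 11) # peak scan

  # duplicate indices are allowed
  a2 <- a; a2$tp[5] <- a2$tp[6]
  class(a2) <- "phase_assignment"
  pv2 <- phase_volumes(series, a2)
  expect_equal(pv2$TP5$voxels[1], pv2$TP6$voxels[1])

  a3 <- a; a3$tp[7] <- 99L
  expect_error(phase_volumes(series, a3), "out of range")
})

test_that("midpoint/onset variants behave as configured", {
  cfg_idx <- phase_sync_config(midpoint = "index")
  # uniform 1 s spacing: index and time midpoints coincide
  expect_equal(define_phases(piecewise_curve(), cfg_idx)$tp,
               define_phases(piecewise_curve())$tp)
  # on a non-uniform grid they can differ
  tt <- c(0:16 * 1.5, 25.5 + 3 * (1:3))
  v <- c(seq(100, 200, by = 10), seq(190, 110, by = -10))
  curve <- enhancement_curve(tt, v)
  a_time <- define_phases(curve)
  a_index <- define_phases(curve, cfg_idx)
  expect_equal(a_time$tp[4], a_index$tp[4])  # peak unaffected
  expect_true(all(diff(a_time$tp) >= 0))
})
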