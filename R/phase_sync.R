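# Synchronization of dynamic series to seven contrast-agent phases, driven
# by the median intensity of a reference vessel (femoral artery or aorta).
# The seven phases: TP1 = second scan (pre-bolus), TP2 = wash-in onset,
# TP3 = mid wash-in, TP4 = arterial peak, TP5 = mid wash-out, TP6 = washout
# end, TP7 = second-to-last scan.

#' Median enhancement curve of a vessel ROI
#'
#' @param series a [dynamic_series()].
#' @param vessel a [roi_mask()] matching the series geometry.
#' @return A list of class \code{enhancement_curve} with \code{times} (s)
#'   and \code{values} (median vessel intensity per scan).
#' @export
median_enhancement_curve <- function(series, vessel) {
  stopifnot(inherits(series, "dynamic_series"), inherits(vessel, "roi_mask"))
  check_same_geometry(vessel, series$volumes[[1]])
  vals <- vapply(series$volumes,
                 function(v) stats::median(v$voxels[vessel$voxels]),
                 numeric(1))
  enhancement_curve(series$times, vals)
}

#' Construct an enhancement curve
#'
#' @param times acquisition times (s), strictly increasing, length >= 7.
#' @param values median ROI intensity per scan; finite.
#' @return An \code{enhancement_curve} object.
#' @export
enhancement_curve <- function(times, values) {
  if (length(times) != length(values)) stop("times and values lengths differ")
  if (length(times) < 7L) stop("an enhancement curve needs >= 7 scans")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(values))) stop("curve values must be finite")
  structure(list(times = as.numeric(times), values = as.numeric(values)),
            class = "enhancement_curve")
}

#' Phase synchronization settings
#'
#' @param rise_fraction relative intensity rise defining bolus arrival and
#'   washout end (default 0.15, i.e. 15 percent above the reference level).
#' @param midpoint one of \code{"time"} (default: TP3/TP5 are nearest to
#'   the midpoint on the acquisition-time axis, which is the appropriate
#'   reading when scan intervals change mid-series) or \code{"index"}.
#' @param onset one of \code{"first_crossing"} (default: TP2 is the
#'   earliest scan at or above the rise threshold, an event semantics
#'   mirrored by the TP6 last-crossing rule) or \code{"nearest"} (scan
#'   whose value is closest to the threshold level).
#' @return A \code{phase_sync_config} object.
#' @export
phase_sync_config <- function(rise_fraction = 0.15,
                              midpoint = c("time", "index"),
                              onset = c("first_crossing", "nearest")) {
  if (!(rise_fraction > 0 && rise_fraction < 1))
    stop("rise_fraction must be in (0, 1)")
  structure(list(rise_fraction = rise_fraction,
                 midpoint = match.arg(midpoint),
                 onset = match.arg(onset)),
            class = "phase_sync_config")
}

# Scan nearest to a target position on the configured axis; ties break to
# the earlier scan.
nearest_scan <- function(curve, lo, hi, cfg) {
  axis <- if (cfg$midpoint == "time") curve$times else seq_along(curve$times)
  target <- (axis[lo] + axis[hi]) / 2
  cand <- seq(lo, hi)
  d <- abs(axis[cand] - target)
  cand[which.min(d)]  # which.min takes the first minimum -> earlier scan
}

#' Define the seven contrast-agent phases from a vessel curve
#'
#' TP1 is the second acquired scan. TP2 is the scan closest to an increase
#' of at least \code{rise_fraction} in median intensity over the mean of
#' the first two scans (first crossing by default). TP4 is the scan with
#' peak intensity (ties to the earliest). TP3 is the scan closest to the
#' center between TP2 and TP4. TP6 is the last scan with intensity at
#' least \code{rise_fraction} above the mean of the last two scans, TP5
#' the scan closest to the center between TP4 and TP6, and TP7 the
#' second-to-last scan. Scan indices are 1-based.
#'
#' @param curve an [enhancement_curve()].
#' @param cfg a [phase_sync_config()].
#' @return A \code{phase_assignment}: list with \code{tp} (7 scan indices,
#'   non-decreasing), \code{times} and \code{values} at those scans.
#' @export
define_phases <- function(curve, cfg = phase_sync_config()) {
  stopifnot(inherits(curve, "enhancement_curve"))
  v <- curve$values
  n <- length(v)
  tp1 <- 2L
  tp7 <- n - 1L

  head_level <- mean(v[1:2]) * (1 + cfg$rise_fraction)
  rising <- which(v >= head_level)
  if (length(rising) == 0L) stop("no bolus detected: curve never rises ",
                                 round(cfg$rise_fraction * 100), "% above baseline")
  tp2 <- if (cfg$onset == "first_crossing") rising[1]
         else which.min(abs(v - head_level))

  tp4 <- which.max(v)  # first maximum on ties: first-pass peak

  tail_level <- mean(v[c(n - 1L, n)]) * (1 + cfg$rise_fraction)
  falling <- which(v >= tail_level)
  if (length(falling) == 0L) stop("no washout detected: curve never exceeds ",
                                  round(cfg$rise_fraction * 100),
                                  "% of the tail level")
  tp6 <- falling[length(falling)]

  tp3 <- nearest_scan(curve, min(tp2, tp4), max(tp2, tp4), cfg)
  tp5 <- nearest_scan(curve, min(tp4, tp6), max(tp4, tp6), cfg)

  tp <- c(tp1, tp2, tp3, tp4, tp5, tp6, tp7)
  if (any(diff(tp) < 0))
    stop("phase ordering violated: indices ", paste(tp, collapse = ", "),
         " are not non-decreasing")
  structure(list(tp = as.integer(tp), times = curve$times[tp],
                 values = v[tp]),
            class = "phase_assignment")
}

#' @export
print.phase_assignment <- function(x, ...) {
  cat("<phase_assignment>\n")
  print(data.frame(phase = paste0("TP", 1:7), scan_index = x$tp,
                   time_s = x$times, value = x$values))
  invisible(x)
}

#' Select the seven phase volumes from a series
#'
#' Duplicate indices are allowed (short series can assign two phases to
#' the same scan); the corresponding volume is simply repeated.
#'
#' @param series a [dynamic_series()].
#' @param assignment a \code{phase_assignment} from [define_phases()].
#' @return Named list of 7 [image_volume()]s, names \code{TP1..TP7}.
#' @export
phase_volumes <- function(series, assignment) {
  stopifnot(inherits(series, "dynamic_series"),
            inherits(assignment, "phase_assignment"))
  n <- length(series$volumes)
  if (any(assignment$tp < 1L | assignment$tp > n))
    stop("phase index out of range for a ", n, "-scan series")
  out <- lapply(assignment$tp, function(i) series$volumes[[i]])
  names(out) <- paste0("TP", 1:7)
  out
}

#' Export helpers for curves and assignments
#'
#' @param curve an [enhancement_curve()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(data.frame(time_s = curve$times,
                              median_intensity = curve$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @param assignment a \code{phase_assignment}.
#' @export
write_phases_csv <- function(assignment, path) {
  utils::write.csv(data.frame(phase = paste0("TP", 1:7),
                              scan_index = assignment$tp,
                              time_s = assignment$times),
                   path, row.names = FALSE)
  invisible(path)
}
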