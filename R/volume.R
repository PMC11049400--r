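#' Image volume
#'
#' A 3D scalar grid with physical geometry. Voxel values are Hounsfield
#' units for CT and arbitrary units for MR. Arrays are stored index-ordered
#' (i, j, k) with one spacing value per axis in millimetres; a single axis
#' convention is used throughout the package and asserted at every boundary.
#'
#' @param voxels 3D numeric array of voxel values; all values must be finite.
#' @param spacing numeric length-3, per-axis voxel size in mm (all > 0).
#' @param origin numeric length-3, physical coordinates of the first voxel (mm).
#' @return An object of class \code{image_volume}.
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("expected 3 dimensions, got ", length(dim(voxels)))
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite values")
  if (any(!is.finite(voxels)))
    stop("voxel values must be finite")
  storage.mode(voxels) <- "double"
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 axes = "ijk"),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

#' Region-of-interest mask
#'
#' A binary mask sharing the geometry of a reference volume. The label
#' records which tissue the ROI delineates: the tumor, healthy reference
#' tissue, or the reference vessel whose median intensity drives phase
#' synchronization.
#'
#' @param voxels logical (or 0/1) 3D array; at least one voxel must be TRUE.
#' @param label one of \code{"tumor"}, \code{"healthy"}, \code{"vessel"}.
#' @param spacing,origin geometry, as for [image_volume()].
#' @return An object of class \code{roi_mask}.
#' @export
roi_mask <- function(voxels, label = c("tumor", "healthy", "vessel"),
                     spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  label <- match.arg(label)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("expected 3 dimensions, got ", length(dim(voxels)))
  storage.mode(voxels) <- "logical"
  if (!any(voxels)) stop("empty ROI: mask has no foreground voxels")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three strictly positive values")
  structure(list(voxels = voxels, label = label, spacing = spacing,
                 origin = as.numeric(origin), axes = "ijk"),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> '%s', %d foreground voxels in %s grid\n",
              x$label, sum(x$voxels), paste(dim(x$voxels), collapse = "x")))
  invisible(x)
}

#' Dynamic contrast-enhanced series
#'
#' An ordered list of same-geometry volumes acquired after contrast
#' injection, with strictly increasing acquisition times in seconds from
#' injection.
#'
#' @param volumes list of [image_volume()] objects sharing geometry.
#' @param times numeric vector of acquisition times (s), strictly increasing.
#' @param modality \code{"CT"} or \code{"MR"}.
#' @return An object of class \code{dynamic_series}.
#' @export
dynamic_series <- function(volumes, times, modality = c("CT", "MR")) {
  modality <- match.arg(modality)
  if (length(volumes) < 7L)
    stop("a dynamic series needs at least 7 volumes, got ", length(volumes))
  if (length(times) != length(volumes))
    stop("times and volumes lengths differ")
  if (any(diff(times) <= 0)) stop("acquisition times must be strictly increasing")
  ref <- volumes[[1]]
  for (v in volumes) {
    if (!inherits(v, "image_volume")) stop("volumes must be image_volume objects")
    check_same_geometry(ref, v)
  }
  structure(list(volumes = volumes, times = as.numeric(times),
                 modality = modality),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  cat(sprintf("<dynamic_series> %s, %d scans spanning %.1f-%.1f s\n",
              x$modality, length(x$volumes), x$times[1],
              x$times[length(x$times)]))
  invisible(x)
}

#' Check that two gridded objects share geometry
#'
#' Errors with the first mismatched axis named; tolerance 1e-6 relative on
#' spacing and origin.
#'
#' @param a,b objects with \code{voxels}, \code{spacing}, \code{origin}.
#' @return invisibly TRUE.
#' @export
check_same_geometry <- function(a, b) {
  da <- dim(a$voxels); db <- dim(b$voxels)
  ax <- c("i", "j", "k")
  for (n in 1:3) {
    if (da[n] != db[n])
      stop(sprintf("geometry mismatch on axis %s: shape %d vs %d",
                   ax[n], da[n], db[n]))
    if (abs(a$spacing[n] - b$spacing[n]) > 1e-6 * max(1, abs(a$spacing[n])))
      stop(sprintf("geometry mismatch on axis %s: spacing %g vs %g",
                   ax[n], a$spacing[n], b$spacing[n]))
  }
  invisible(TRUE)
}

#' Propagate an ROI mask across a dynamic series
#'
#' Series volumes come from one session on one grid, so masks carry over as
#' identity copies: no registration is performed and the foreground voxel
#' count is conserved at every timepoint. The geometry-equality precondition
#' replaces visual inspection of the propagated masks.
#'
#' @param mask a [roi_mask()] matching the series geometry.
#' @param series a [dynamic_series()].
#' @return A list with one [roi_mask()] per volume in the series.
#' @export
propagate_mask <- function(mask, series) {
  stopifnot(inherits(mask, "roi_mask"), inherits(series, "dynamic_series"))
  check_same_geometry(mask, series$volumes[[1]])
  replicate(length(series$volumes), mask, simplify = FALSE)
}
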