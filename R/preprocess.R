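# Preprocessing ahead of feature extraction: optional whole-volume
# intensity normalization (MR), resampling to isotropic spacing (cubic
# interpolation for images, nearest neighbor for masks), and cropping to
# the mask bounding box plus a padding margin.

#' Extraction configuration presets
#'
#' The CT preset: bin width 25 HU, voxel array shift 1000, resampling to
#' 1 mm isotropic, pad distance 10 voxels, LoG sigmas 1-5 mm, 8 wavelet
#' sub-bands, no normalization: 14 image sets, 86 features each, 1204
#' features per ROI. The MR preset: bin width 5, shift 300, 2 mm isotropic,
#' z-score normalization scaled by 100, LoG sigmas 2-5 mm: 13 image sets,
#' 1118 features.
#'
#' @param modality "CT" or "MR".
#' @return A list of class \code{extraction_config}.
#' @export
extraction_config <- function(modality = c("CT", "MR")) {
  modality <- match.arg(modality)
  cfg <- if (modality == "CT") {
    list(modality = "CT", bin_width = 25, voxel_array_shift = 1000,
         resampled_spacing = c(1, 1, 1), pad_distance = 10L,
         normalize = FALSE, normalize_scale = 100,
         log_sigmas = c(1, 2, 3, 4, 5), wavelet = TRUE,
         interpolation = "cubic")
  } else {
    list(modality = "MR", bin_width = 5, voxel_array_shift = 300,
         resampled_spacing = c(2, 2, 2), pad_distance = 10L,
         normalize = TRUE, normalize_scale = 100,
         log_sigmas = c(2, 3, 4, 5), wavelet = TRUE,
         interpolation = "cubic")
  }
  structure(cfg, class = "extraction_config")
}

#' Z-score normalize a volume
#'
#' Whole-volume standardization (subtract mean, divide by sd) multiplied
#' by \code{scale}; used for MR intensities, which lack a calibrated scale.
#'
#' @param volume an [image_volume()].
#' @param scale multiplier applied after standardization.
#' @return A normalized [image_volume()].
#' @export
normalize_volume <- function(volume, scale = 100) {
  v <- volume$voxels
  s <- stats::sd(as.vector(v))
  if (s == 0) stop("zero-variance image: cannot normalize")
  image_volume((v - mean(v)) / s * scale, volume$spacing, volume$origin)
}

# Keys cubic convolution kernel (a = -0.5); interpolating, so sampling on
# the input grid reproduces it exactly.
cubic_weight <- function(s) {
  s <- abs(s)
  w <- numeric(length(s))
  a <- -0.5
  i1 <- s <= 1
  w[i1] <- (a + 2) * s[i1]^3 - (a + 3) * s[i1]^2 + 1
  i2 <- s > 1 & s < 2
  w[i2] <- a * s[i2]^3 - 5 * a * s[i2]^2 + 8 * a * s[i2] - 4 * a
  w
}

# Per-axis resampling weight matrix mapping n_old samples at spacing
# sp_old to samples at spacing sp_new on the same physical extent.
resample_weights <- function(n_old, sp_old, sp_new, method = c("cubic", "nearest")) {
  method <- match.arg(method)
  n_new <- max(1L, as.integer(round(n_old * sp_old / sp_new)))
  # positions of new samples in old index coordinates (1-based)
  pos <- 1 + (seq_len(n_new) - 1) * sp_new / sp_old
  if (method == "nearest") {
    idx <- pmin(pmax(round(pos), 1L), n_old)
    W <- matrix(0, n_new, n_old)
    W[cbind(seq_len(n_new), idx)] <- 1
    return(W)
  }
  W <- matrix(0, n_new, n_old)
  for (r in seq_len(n_new)) {
    base <- floor(pos[r])
    taps <- (base - 1L):(base + 2L)
    w <- cubic_weight(pos[r] - taps)
    taps <- pmin(pmax(taps, 1L), n_old)  # clamp = replicate edges
    for (t in seq_along(taps)) W[r, taps[t]] <- W[r, taps[t]] + w[t]
  }
  W
}

apply_axis_matrix <- function(arr, W, axis) {
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  d <- dim(a)
  res <- W %*% matrix(a, nrow = d[1])
  res <- array(res, dim = c(nrow(W), d[2], d[3]))
  aperm(res, order(perm))
}

#' Resample a volume or mask to a target spacing
#'
#' Separable cubic (Keys) interpolation for images; nearest neighbor for
#' masks. If the spacing already matches the target, the input is
#' returned unchanged.
#'
#' @param x an [image_volume()] or [roi_mask()].
#' @param new_spacing numeric length-3 target spacing in mm.
#' @return The resampled object (same class as \code{x}).
#' @export
resample_to <- function(x, new_spacing) {
  new_spacing <- rep_len(as.numeric(new_spacing), 3L)
  if (max(abs(x$spacing - new_spacing)) < 1e-9) return(x)
  is_mask <- inherits(x, "roi_mask")
  method <- if (is_mask) "nearest" else "cubic"
  arr <- if (is_mask) x$voxels + 0 else x$voxels
  for (ax in 1:3) {
    W <- resample_weights(dim(arr)[ax], x$spacing[ax], new_spacing[ax], method)
    arr <- apply_axis_matrix(arr, W, ax)
  }
  if (is_mask) {
    if (!any(arr > 0.5)) stop("mask empty after resampling")
    roi_mask(arr > 0.5, x$label, new_spacing, x$origin)
  } else {
    image_volume(arr, new_spacing, x$origin)
  }
}

mask_bbox <- function(mask_voxels) {
  w <- which(mask_voxels, arr.ind = TRUE)
  rbind(lo = apply(w, 2, min), hi = apply(w, 2, max))
}

#' Crop a volume and mask to the mask bounding box plus padding
#'
#' @param volume an [image_volume()].
#' @param mask a matching [roi_mask()].
#' @param pad padding in voxels added on each side (clipped at the volume
#'   boundary).
#' @return List with cropped \code{volume} and \code{mask}.
#' @export
crop_to_mask <- function(volume, mask, pad = 10L) {
  check_same_geometry(volume, mask)
  bb <- mask_bbox(mask$voxels)
  d <- dim(volume$voxels)
  lo <- pmax(bb["lo", ] - pad, 1L)
  hi <- pmin(bb["hi", ] + pad, d)
  vv <- volume$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  mv <- mask$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  origin <- volume$origin + (lo - 1L) * volume$spacing
  list(volume = image_volume(vv, volume$spacing, origin),
       mask = roi_mask(mv, mask$label, mask$spacing, origin))
}

#' Preprocess a volume/mask pair for feature extraction
#'
#' MR path: whole-volume z-score normalization scaled by
#' \code{normalize_scale}. Both paths: resample image (cubic) and mask
#' (nearest neighbor) to the configured isotropic spacing, then crop to
#' the mask bounding box plus \code{pad_distance}.
#'
#' @param volume an [image_volume()].
#' @param mask a matching [roi_mask()].
#' @param cfg an [extraction_config()].
#' @return List with preprocessed \code{volume} and \code{mask}.
#' @export
preprocess <- function(volume, mask, cfg = extraction_config("CT")) {
  check_same_geometry(volume, mask)
  if (isTRUE(cfg$normalize))
    volume <- normalize_volume(volume, cfg$normalize_scale)
  volume <- resample_to(volume, cfg$resampled_spacing)
  mask <- resample_to(mask, cfg$resampled_spacing)
  check_same_geometry(volume, mask)
  crop_to_mask(volume, mask, cfg$pad_distance)
}
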