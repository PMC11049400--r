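# Full feature battery per ROI: preprocess, build the image sets
# (original + LoG scales + 8 wavelet sub-bands), then 86 features per set
# (18 first-order + 22 GLCM + 14 GLDM + 16 GLRLM + 16 GLSZM). Shape
# features are excluded by construction: masks are propagated unchanged
# across a series, so shape cannot vary with phase.

#' Build the derived image sets for feature extraction
#'
#' @param volume a preprocessed [image_volume()].
#' @param cfg an [extraction_config()].
#' @return Named list of [image_volume()]s: \code{original},
#'   \code{log-sigma-<s>-mm-3D} per configured sigma, and
#'   \code{wavelet-LLL} .. \code{wavelet-HHH} when wavelets are enabled.
#' @export
image_sets <- function(volume, cfg = extraction_config("CT")) {
  sets <- list(original = volume)
  for (s in cfg$log_sigmas)
    sets[[sprintf("log-sigma-%g-mm-3D", s)]] <- log_filter(volume, s)
  if (isTRUE(cfg$wavelet)) {
    wb <- wavelet_subbands(volume)
    names(wb) <- paste0("wavelet-", names(wb))
    sets <- c(sets, wb)
  }
  sets
}

# 86 features for one image set: named vector, names class_Feature.
features_one_set <- function(voxels, mask, cfg, voxel_volume) {
  vals <- voxels[mask]
  fo <- first_order_features(vals, cfg$bin_width, cfg$voxel_array_shift,
                             voxel_volume)
  # texture matrices only see in-mask voxels: restrict to the tight mask
  # bounding box so the matrix builders do not scan the padding margin
  bb <- mask_bbox(mask)
  mask <- mask[bb["lo", 1]:bb["hi", 1], bb["lo", 2]:bb["hi", 2],
               bb["lo", 3]:bb["hi", 3], drop = FALSE]
  voxels <- voxels[bb["lo", 1]:bb["hi", 1], bb["lo", 2]:bb["hi", 2],
                   bb["lo", 3]:bb["hi", 3], drop = FALSE]
  lv <- array(NA_integer_, dim = dim(voxels))
  lv[mask] <- discretize(voxels[mask], cfg$bin_width)
  parts <- list(firstorder = fo,
                glcm = glcm_features(lv, mask),
                gldm = gldm_features(lv, mask),
                glrlm = glrlm_features(lv, mask),
                glszm = glszm_features(lv, mask))
  out <- numeric(0); flags <- character(0)
  for (cls in names(parts)) {
    v <- parts[[cls]]
    nm <- paste0(cls, "_", names(v))
    fl <- attr(v, "flagged")
    if (length(fl)) flags <- c(flags, paste0(cls, "_", fl))
    o <- as.numeric(v); names(o) <- nm
    out <- c(out, o)
  }
  attr(out, "flagged") <- flags
  out
}

#' Extract the full feature vector for one ROI
#'
#' Preprocesses the volume/mask pair, builds the image sets and computes
#' the 86-feature battery on each: the CT preset yields 14 x 86 = 1204
#' features, the MR preset 13 x 86 = 1118, in a stable deterministic
#' order. Feature names follow the
#' \code{<imageset>_<class>_<Feature>} convention
#' (e.g. \code{wavelet-LLH_glrlm_ShortRunEmphasis}).
#'
#' @param volume an [image_volume()].
#' @param mask a matching [roi_mask()].
#' @param cfg an [extraction_config()].
#' @return Named numeric vector with a \code{"flagged"} attribute listing
#'   features whose value is a degenerate-input fallback.
#' @export
extract_all <- function(volume, mask, cfg = extraction_config("CT")) {
  pp <- preprocess(volume, mask, cfg)
  sets <- image_sets(pp$volume, cfg)
  vv <- prod(pp$volume$spacing)
  out <- numeric(0); flags <- character(0)
  for (nm in names(sets)) {
    f <- features_one_set(sets[[nm]]$voxels, pp$mask$voxels, cfg, vv)
    fl <- attr(f, "flagged")
    if (length(fl)) flags <- c(flags, paste0(nm, "_", fl))
    o <- as.numeric(f); names(o) <- paste0(nm, "_", names(f))
    out <- c(out, o)
  }
  attr(out, "flagged") <- flags
  out
}

#' Per-phase feature table for a phantom patient
#'
#' Synchronizes the series to the seven phases via the vessel ROI, then
#' extracts the full feature battery from the tumor and healthy ROIs at
#' each phase volume.
#'
#' @param patient a \code{phantom_patient} from [generate_patient()].
#' @param cfg an [extraction_config()].
#' @param sync_cfg a [phase_sync_config()].
#' @param rois which ROIs to extract (default tumor + healthy).
#' @return Long-format data.frame: subject, roi, phase (1-7), scan_index,
#'   feature, value, flag.
#' @export
extract_patient_features <- function(patient, cfg = extraction_config("CT"),
                                     sync_cfg = phase_sync_config(),
                                     rois = c("tumor", "healthy")) {
  curve <- median_enhancement_curve(patient$series, patient$masks$vessel)
  assignment <- define_phases(curve, sync_cfg)
  vols <- phase_volumes(patient$series, assignment)
  rows <- list()
  for (roi in rois) {
    for (ph in 1:7) {
      fv <- extract_all(vols[[ph]], patient$masks[[roi]], cfg)
      flags <- attr(fv, "flagged")
      rows[[length(rows) + 1L]] <- data.frame(
        subject = patient$id, roi = roi, phase = ph,
        scan_index = assignment$tp[ph],
        feature = names(fv), value = as.numeric(fv),
        flag = names(fv) %in% flags,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Cohort-level long feature table
#'
#' @param patients list of \code{phantom_patient}s (see [generate_cohort()]).
#' @param cfg an [extraction_config()].
#' @param sync_cfg a [phase_sync_config()].
#' @param verbose print one line per patient.
#' @return Long-format data.frame over all patients (see
#'   [extract_patient_features()]).
#' @export
cohort_feature_table <- function(patients, cfg = extraction_config("CT"),
                                 sync_cfg = phase_sync_config(),
                                 verbose = FALSE) {
  out <- vector("list", length(patients))
  for (i in seq_along(patients)) {
    if (verbose) message("extracting features: ", patients[[i]]$id)
    out[[i]] <- extract_patient_features(patients[[i]], cfg, sync_cfg)
  }
  do.call(rbind, out)
}
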