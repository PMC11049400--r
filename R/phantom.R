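# Synthetic DCE phantom cohorts with known ground truth. The phantom
# emulates a perfusion-CT acquisition: a reference vessel carrying a
# gamma-variate bolus with per-patient jitter in arrival time and peak
# amplitude, plus tumor and healthy-tissue ROIs following compartmental
# uptake curves with a spatially correlated texture field whose amplitude
# is partly coupled to enhancement, so texture genuinely changes with
# contrast phase.

#' Run a function with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so generators are
#' deterministic without clobbering the session stream.
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

#' Phantom cohort specification
#'
#' Defaults describe the dceCT study conditions the phantom emulates:
#' the first 20 scans at 1.5 s intervals and the remainder at 3 s; arterial
#' peaks between 15 and 26 s with peak values between 520 and 827 HU.
#' Kinetic defaults give the tumor a rapid, intense uptake (peak
#' enhancement on the order of +100 HU) and healthy tissue a weaker one
#' (around +40 HU), with identical pre-contrast appearance so any
#' tumor/healthy separability is phase-gated by the bolus.
#'
#' @param grid_shape integer length-3 voxel grid (default 32^3).
#' @param spacing voxel size in mm.
#' @param n_scans number of dynamic scans (>= 10).
#' @param aif_alpha gamma-variate shape parameter (unitless).
#' @param arrival_range bolus arrival time t0 range, seconds.
#' @param peak_time_range range for the arterial peak time, seconds.
#' @param peak_value_range range for the arterial peak intensity, HU.
#' @param vessel_baseline,tissue_baseline pre-contrast intensities, HU.
#' @param tumor_kin,healthy_kin named vectors c(k_in=, k_out=) in 1/s.
#' @param texture_length texture correlation length, mm.
#' @param texture_amp static texture amplitude (HU, 1 sd of the field).
#' @param texture_enh_frac fraction of local enhancement added to the
#'   texture amplitude (unitless); this is what makes texture features
#'   phase-dependent.
#' @param noise_sd additive Gaussian noise, HU.
#' @param n_patients cohort size.
#' @param seed master seed for the cohort.
#' @param modality "CT" (bolus timing grid, HU) or "MR" (uniform 4.22 s
#'   grid, arbitrary units; otherwise identical mechanics).
#' @return A validated list of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 32L),
                         spacing = c(1, 1, 1),
                         n_scans = 26L,
                         aif_alpha = 3,
                         arrival_range = c(4, 8),
                         peak_time_range = c(15, 26),
                         peak_value_range = c(520, 827),
                         vessel_baseline = 60,
                         tissue_baseline = 35,
                         tumor_kin = c(k_in = 0.010, k_out = 0.025),
                         healthy_kin = c(k_in = 0.004, k_out = 0.025),
                         texture_length = 3,
                         texture_amp = 8,
                         texture_enh_frac = 0.10,
                         noise_sd = 10,
                         n_patients = 7L,
                         seed = 0L,
                         modality = c("CT", "MR")) {
  modality <- match.arg(modality)
  tumor_kin <- kin_vec(tumor_kin)
  healthy_kin <- kin_vec(healthy_kin)
  spec <- list(grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
               n_scans = as.integer(n_scans), aif_alpha = aif_alpha,
               arrival_range = arrival_range, peak_time_range = peak_time_range,
               peak_value_range = peak_value_range,
               vessel_baseline = vessel_baseline, tissue_baseline = tissue_baseline,
               tumor_kin = tumor_kin, healthy_kin = healthy_kin,
               texture_length = texture_length, texture_amp = texture_amp,
               texture_enh_frac = texture_enh_frac, noise_sd = noise_sd,
               n_patients = as.integer(n_patients), seed = as.integer(seed),
               modality = modality)
  validate_phantom_spec(spec)
}

# Coerce a kinetics specification (named vector, list, or bare length-2
# numeric in (k_in, k_out) order, e.g. after a YAML round trip) to the
# canonical named vector.
kin_vec <- function(x) {
  x <- unlist(x)
  if (is.null(names(x)) || !all(c("k_in", "k_out") %in% names(x))) {
    if (length(x) != 2L) stop("kinetics must provide k_in and k_out")
    names(x) <- c("k_in", "k_out")
  }
  x[c("k_in", "k_out")]
}

validate_phantom_spec <- function(spec) {
  stopifnot(length(spec$grid_shape) == 3L, all(spec$grid_shape >= 8L))
  if (spec$n_scans < 10L) stop("n_scans must be >= 10")
  rates <- c(spec$tumor_kin, spec$healthy_kin)
  if (any(rates < 0)) stop("kinetic rates must be >= 0")
  if (spec$aif_alpha <= 0) stop("aif_alpha must be > 0")
  if (diff(spec$peak_time_range) < 0 || diff(spec$peak_value_range) < 0)
    stop("ranges must be non-decreasing")
  if (spec$peak_time_range[1] < spec$arrival_range[2])
    stop("peak_time_range must lie after the latest possible arrival")
  if (spec$noise_sd < 0 || spec$texture_amp < 0 || spec$texture_enh_frac < 0)
    stop("noise and texture amplitudes must be >= 0")
  structure(spec, class = "phantom_spec")
}

#' Acquisition time grid
#'
#' CT: first 20 scans at 1.5 s intervals starting at 0 s, the rest at 3 s
#' intervals. MR: uniform intervals of \code{dt} seconds.
#'
#' @param n_scans number of scans.
#' @param modality "CT" or "MR".
#' @param dt MR temporal resolution in seconds.
#' @return Numeric vector of acquisition times (s).
#' @export
scan_times <- function(n_scans, modality = "CT", dt = 4.22) {
  if (modality == "MR") return(dt * (seq_len(n_scans) - 1))
  i <- seq_len(n_scans) - 1
  ifelse(i < 20, 1.5 * i, 1.5 * 19 + 3 * (i - 19))
}

#' Gamma-variate arterial input function
#'
#' First-pass bolus model
#' \eqn{A ((t-t_0)/(\alpha\beta))^\alpha \exp(\alpha - (t-t_0)/\beta)} for
#' \eqn{t > t_0} and 0 before arrival. The curve peaks at exactly \eqn{A}
#' when \eqn{t = t_0 + \alpha\beta}. Recirculation is not modelled.
#'
#' @param t time(s) in seconds; vectorized.
#' @param t0 bolus arrival time (s).
#' @param A peak amplitude above baseline (HU).
#' @param alpha shape (> 0, unitless).
#' @param beta time scale (> 0, s).
#' @return Enhancement in HU at each \code{t}.
#' @export
gamma_variate_aif <- function(t, t0, A, alpha, beta) {
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  dt <- t - t0
  out <- numeric(length(t))
  pos <- dt > 0
  out[pos] <- A * (dt[pos] / (alpha * beta))^alpha * exp(alpha - dt[pos] / beta)
  out
}

#' Compartmental tissue enhancement curve
#'
#' One-compartment uptake: baseline plus
#' \eqn{k_{in} \int_0^t \mathrm{aif}(s) e^{-k_{out}(t-s)} ds}, evaluated by
#' trapezoidal quadrature on an internal fine grid (step \code{dt_quad}).
#'
#' @param aif a function of time (s) returning enhancement (HU).
#' @param baseline pre-contrast intensity (HU).
#' @param k_in influx rate (1/s); 0 gives a flat curve at baseline.
#' @param k_out efflux rate (1/s); must be > 0 when \code{k_in > 0}.
#' @param times output times (s).
#' @param dt_quad quadrature step (s).
#' @return Numeric vector of tissue intensities at \code{times}.
#' @export
tissue_curve <- function(aif, baseline, k_in, k_out, times, dt_quad = 0.25) {
  if (k_in < 0 || k_out < 0) stop("kinetic rates must be >= 0")
  if (k_in > 0 && k_out <= 0) stop("k_out must be > 0 when k_in > 0")
  if (k_in == 0) return(rep(baseline, length(times)))
  tmax <- max(times)
  grid <- seq(0, tmax, by = dt_quad)
  if (grid[length(grid)] < tmax) grid <- c(grid, tmax)
  a <- aif(grid)
  vapply(times, function(t) {
    sub <- grid[grid <= t]
    if (length(sub) < 2L) return(baseline)
    integrand <- a[seq_along(sub)] * exp(-k_out * (t - sub))
    w <- diff(sub)
    baseline + k_in * sum(w * (integrand[-1] + integrand[-length(sub)]) / 2)
  }, numeric(1))
}

# Spatially correlated zero-mean unit-sd random field: white noise smoothed
# with a separable Gaussian of physical correlation length `length_mm`.
correlated_field <- function(shape, spacing, length_mm) {
  field <- array(stats::rnorm(prod(shape)), dim = shape)
  if (length_mm > 0) {
    for (ax in 1:3) {
      sig <- length_mm / spacing[ax]
      field <- convolve_axis(field, gaussian_kernel(sig, order = 0L), ax)
    }
  }
  (field - mean(field)) / stats::sd(as.vector(field))
}

sphere_mask <- function(shape, center, radius) {
  i <- seq_len(shape[1]); j <- seq_len(shape[2]); k <- seq_len(shape[3])
  d2 <- outer(outer((i - center[1])^2, (j - center[2])^2, "+"),
              (k - center[3])^2, "+")
  array(d2 <= radius^2, dim = shape)
}

cylinder_mask <- function(shape, center_ij, radius, k_range) {
  i <- seq_len(shape[1]); j <- seq_len(shape[2])
  d2 <- outer((i - center_ij[1])^2, (j - center_ij[2])^2, "+")
  m <- array(FALSE, dim = shape)
  for (k in k_range) m[, , k] <- d2 <= radius^2
  m
}

#' Generate one phantom patient
#'
#' Vessel voxels follow a per-patient jittered gamma-variate bolus on top
#' of the vessel baseline; tumor and healthy voxels follow their
#' compartmental curves plus a static spatially correlated texture field
#' whose amplitude grows with local enhancement; everything gets additive
#' Gaussian noise. Deterministic for a fixed seed.
#'
#' @param spec a [phantom_spec()].
#' @param patient_seed integer seed for this patient.
#' @param id patient identifier stored in the result.
#' @return A list of class \code{phantom_patient} with elements
#'   \code{series} ([dynamic_series()]), \code{masks} (tumor/healthy/vessel
#'   [roi_mask()]s) and \code{ground_truth} (drawn parameters and true
#'   per-ROI curves on the scan grid).
#' @export
generate_patient <- function(spec, patient_seed, id = sprintf("P%03d", patient_seed)) {
  spec <- validate_phantom_spec(spec)
  shape <- spec$grid_shape
  times <- scan_times(spec$n_scans, spec$modality)
  with_seed(patient_seed, {
    t_peak <- stats::runif(1, spec$peak_time_range[1], spec$peak_time_range[2])
    peak_hu <- stats::runif(1, spec$peak_value_range[1], spec$peak_value_range[2])
    t0 <- stats::runif(1, spec$arrival_range[1], min(spec$arrival_range[2], t_peak - 1))
    beta <- (t_peak - t0) / spec$aif_alpha
    A <- peak_hu - spec$vessel_baseline
    aif <- function(t) gamma_variate_aif(t, t0, A, spec$aif_alpha, beta)

    tumor_curve <- tissue_curve(aif, spec$tissue_baseline,
                                spec$tumor_kin[["k_in"]], spec$tumor_kin[["k_out"]], times)
    healthy_curve <- tissue_curve(aif, spec$tissue_baseline,
                                  spec$healthy_kin[["k_in"]], spec$healthy_kin[["k_out"]], times)
    vessel_curve <- spec$vessel_baseline + aif(times)

    c8 <- shape %/% 3.5
    tumor_m <- sphere_mask(shape, c(c8[1], c8[2], shape[3] %/% 2), radius = min(shape) / 6.4)
    healthy_m <- sphere_mask(shape, c(shape[1] - c8[1], shape[2] - c8[2], shape[3] %/% 2),
                             radius = min(shape) / 6.4)
    vessel_m <- cylinder_mask(shape, c(shape[1] %/% 2, shape[2] %/% 2),
                              radius = min(shape) / 10.7,
                              k_range = seq(2L, shape[3] - 1L))
    stopifnot(!any(tumor_m & healthy_m), !any(tumor_m & vessel_m),
              !any(healthy_m & vessel_m))

    tex_tumor <- correlated_field(shape, spec$spacing, spec$texture_length)
    tex_healthy <- correlated_field(shape, spec$spacing, spec$texture_length)

    volumes <- vector("list", spec$n_scans)
    for (s in seq_len(spec$n_scans)) {
      vol <- array(0, dim = shape)
      vol[vessel_m] <- vessel_curve[s]
      enh_t <- tumor_curve[s] - spec$tissue_baseline
      enh_h <- healthy_curve[s] - spec$tissue_baseline
      vol[tumor_m] <- tumor_curve[s] +
        tex_tumor[tumor_m] * (spec$texture_amp + spec$texture_enh_frac * enh_t)
      vol[healthy_m] <- healthy_curve[s] +
        tex_healthy[healthy_m] * (spec$texture_amp + spec$texture_enh_frac * enh_h)
      if (spec$noise_sd > 0)
        vol <- vol + array(stats::rnorm(prod(shape), sd = spec$noise_sd), dim = shape)
      volumes[[s]] <- image_volume(vol, spec$spacing)
    }

    series <- dynamic_series(volumes, times, spec$modality)
    masks <- list(
      tumor = roi_mask(tumor_m, "tumor", spec$spacing),
      healthy = roi_mask(healthy_m, "healthy", spec$spacing),
      vessel = roi_mask(vessel_m, "vessel", spec$spacing))
    ground_truth <- list(
      t0 = t0, beta = beta, alpha = spec$aif_alpha, A = A,
      t_peak = t_peak, peak_hu = peak_hu, times = times,
      curves = list(tumor = tumor_curve, healthy = healthy_curve,
                    vessel = vessel_curve),
      peak_scan = which.max(vessel_curve))
    structure(list(id = id, seed = patient_seed, series = series,
                   masks = masks, ground_truth = ground_truth),
              class = "phantom_patient")
  })
}

patient_seed_for <- function(master_seed, i) {
  (as.numeric(master_seed) * 10007 + i * 97) %% 2147483629
}

#' Generate a phantom cohort
#'
#' Per-patient seeds are derived deterministically from the master seed, so
#' two cohorts from the same spec are identical. Optionally writes each
#' patient's series and masks as NRRD files plus a cohort manifest.
#'
#' @param spec a [phantom_spec()].
#' @param outdir if not NULL, write NRRD volumes/masks and
#'   \code{manifest.csv} under this directory.
#' @return List of \code{phantom_patient} objects, with the manifest data
#'   frame attached as attribute \code{"manifest"}.
#' @export
generate_cohort <- function(spec, outdir = NULL) {
  spec <- validate_phantom_spec(spec)
  if (spec$n_patients < 1L) stop("n_patients must be >= 1")
  patients <- vector("list", spec$n_patients)
  rows <- vector("list", spec$n_patients)
  for (i in seq_len(spec$n_patients)) {
    ps <- patient_seed_for(spec$seed, i)
    p <- generate_patient(spec, ps, id = sprintf("P%03d", i))
    patients[[i]] <- p
    row <- data.frame(id = p$id, seed = ps,
                      t0 = p$ground_truth$t0, t_peak = p$ground_truth$t_peak,
                      peak_hu = p$ground_truth$peak_hu,
                      peak_scan = p$ground_truth$peak_scan,
                      n_scans = spec$n_scans, stringsAsFactors = FALSE)
    if (!is.null(outdir)) {
      pdir <- file.path(outdir, p$id)
      dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
      for (s in seq_along(p$series$volumes))
        write_volume(p$series$volumes[[s]],
                     file.path(pdir, sprintf("scan_%02d.nrrd", s)))
      for (lab in names(p$masks))
        write_volume(p$masks[[lab]], file.path(pdir, paste0("mask_", lab, ".nrrd")))
      row$path <- pdir
    }
    rows[[i]] <- row
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(outdir))
    utils::write.csv(manifest, file.path(outdir, "manifest.csv"), row.names = FALSE)
  attr(patients, "manifest") <- manifest
  patients
}
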