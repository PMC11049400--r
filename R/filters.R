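# Image filters used to build the derived image sets: Laplacian of
# Gaussian at physical sigmas, and a single-level 3D separable wavelet
# decomposition (Coiflet-1) into the eight LLL..HHH sub-bands.

# Apply a 1D kernel along one axis of a 3D array with replicate padding.
convolve_axis <- function(arr, kernel, axis) {
  r <- (length(kernel) - 1L) %/% 2L
  if (r == 0L) return(arr * kernel)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  d <- dim(a)
  m <- matrix(a, nrow = d[1])
  n <- d[1]
  idx <- c(rep(1L, r), seq_len(n), rep(n, r))  # replicate edges
  p <- m[idx, , drop = FALSE]
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (k in seq_along(kernel))
    out <- out + kernel[k] * p[(k - 1L) + seq_len(n), , drop = FALSE]
  res <- array(out, dim = d)
  aperm(res, order(perm))
}

# Sampled Gaussian kernel (order 0) or its second derivative (order 2).
# Order-0 kernels are normalized to sum 1; order-2 kernels to zero sum so a
# constant image maps to zero response.
gaussian_kernel <- function(sigma, order = 0L) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  if (order == 0L) return(g / sum(g))
  g2 <- (x^2 / sigma^4 - 1 / sigma^2) * g / (sigma * sqrt(2 * pi))
  g2 - mean(g2)
}

#' Laplacian-of-Gaussian filter at a physical scale
#'
#' Computes the scale-normalized LoG response
#' \eqn{\sigma^2 \nabla^2 (G_\sigma * I)} with sigma given in millimetres
#' and converted to voxel units per axis via the volume spacing
#' (\code{sigma_vox = sigma / spacing}), so the emphasized texture scale is
#' physical. Separable implementation (second-derivative-of-Gaussian along
#' one axis, plain Gaussian along the others, summed over axes) with
#' replicate boundary handling. The \eqn{\sigma^2} factor makes responses
#' comparable across scales.
#'
#' @param volume an [image_volume()].
#' @param sigma filter scale in mm (> 0).
#' @return An [image_volume()] with the LoG response.
#' @export
log_filter <- function(volume, sigma) {
  stopifnot(inherits(volume, "image_volume"), sigma > 0)
  sp <- volume$spacing
  acc <- array(0, dim = dim(volume$voxels))
  for (ax in 1:3) {
    r <- volume$voxels
    for (other in 1:3) {
      sig_vox <- sigma / sp[other]
      kern <- if (other == ax) gaussian_kernel(sig_vox, order = 2L)
              else gaussian_kernel(sig_vox, order = 0L)
      r <- convolve_axis(r, kern, other)
    }
    # voxel-unit second derivative -> physical mm^-2
    acc <- acc + r / sp[ax]^2
  }
  image_volume(sigma^2 * acc, volume$spacing, volume$origin)
}

# Coiflet-1 orthonormal decomposition filters.
coif1_lo <- c(-0.015655728135464787, -0.07273261951252645,
               0.3848648468648578,    0.8525720202116004,
               0.33789766245748187,  -0.07273261951252645)
coif1_hi <- rev(coif1_lo) * c(1, -1, 1, -1, 1, -1)

# Periodized decimated analysis step along one axis (length must be even).
dwt_axis <- function(arr, kernel, axis) {
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  d <- dim(a)
  n <- d[1]
  if (n %% 2L != 0L) stop("dwt_axis requires even axis length")
  m <- matrix(a, nrow = n)
  half <- n %/% 2L
  out <- matrix(0, nrow = half, ncol = ncol(m))
  base <- 2L * (seq_len(half) - 1L)          # 0-based even positions
  for (k in seq_along(kernel)) {
    rows <- ((base + (k - 1L)) %% n) + 1L    # circular indexing
    out <- out + kernel[k] * m[rows, , drop = FALSE]
  }
  res <- array(out, dim = c(half, d[2], d[3]))
  aperm(res, order(perm))
}

pad_to_even <- function(arr) {
  d <- dim(arr)
  pad <- d %% 2L
  if (!any(pad == 1L)) return(arr)
  out <- array(0, dim = d + pad)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- arr
  if (pad[1]) out[d[1] + 1L, , ] <- out[d[1], , ]
  if (pad[2]) out[, d[2] + 1L, ] <- out[, d[2], ]
  if (pad[3]) out[, , d[3] + 1L] <- out[, , d[3]]
  out
}

#' Single-level 3D discrete wavelet transform (Coiflet-1)
#'
#' Decimated orthonormal decomposition with periodic boundary handling;
#' odd axis lengths are first padded to even by edge replication. Returns
#' the eight coefficient arrays at half resolution, labelled by the
#' low/high-pass choice along each of the three axes. Because the filter
#' bank is orthonormal and periodized, total energy is conserved across
#' the eight sub-bands for even-sized inputs.
#'
#' @param voxels 3D numeric array.
#' @return Named list of 8 coefficient arrays
#'   (\code{LLL}, \code{LLH}, ..., \code{HHH}).
#' @export
dwt3 <- function(voxels) {
  a <- pad_to_even(voxels)
  out <- list()
  for (b1 in c("L", "H")) {
    s1 <- dwt_axis(a, if (b1 == "L") coif1_lo else coif1_hi, 1L)
    for (b2 in c("L", "H")) {
      s2 <- dwt_axis(s1, if (b2 == "L") coif1_lo else coif1_hi, 2L)
      for (b3 in c("L", "H")) {
        s3 <- dwt_axis(s2, if (b3 == "L") coif1_lo else coif1_hi, 3L)
        out[[paste0(b1, b2, b3)]] <- s3
      }
    }
  }
  out[c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")]
}

# Undecimated analysis step along one axis: centered filter window with
# symmetric (mirror) boundary handling, so responses near the crop edge
# depend only on local image content and the step is shift-equivariant in
# the interior.
swt_axis <- function(arr, kernel, axis) {
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  d <- dim(a)
  n <- d[1]
  m <- matrix(a, nrow = n)
  out <- matrix(0, nrow = n, ncol = ncol(m))
  off <- length(kernel) %/% 2L
  for (k in seq_along(kernel)) {
    rows <- seq_len(n) + (k - 1L) - off
    # mirror indices (whole-sample reflection) into 1..n
    rows <- ifelse(rows < 1L, 2L - rows, rows)
    rows <- ifelse(rows > n, 2L * n - rows, rows)
    out <- out + kernel[k] * m[rows, , drop = FALSE]
  }
  aperm(array(out, dim = d), order(perm))
}

#' Wavelet sub-band image set
#'
#' Single-level undecimated (stationary) 3D wavelet decomposition with the
#' Coiflet-1 filter pair and periodic boundary handling: the low/high-pass
#' filter is applied along each axis without downsampling, so every
#' sub-band has the size of the input and the decomposition is
#' shift-equivariant. Shift-equivariance matters for feature extraction:
#' sub-band statistics inside an ROI must not depend on how the ROI
#' happens to align with a decimation grid. For the decimated orthonormal
#' transform (energy-preserving across sub-bands) see [dwt3()].
#'
#' @param volume an [image_volume()].
#' @return Named list of 8 [image_volume()]s labelled LLL..HHH.
#' @export
wavelet_subbands <- function(volume) {
  stopifnot(inherits(volume, "image_volume"))
  a <- volume$voxels
  out <- list()
  for (b1 in c("L", "H")) {
    s1 <- swt_axis(a, if (b1 == "L") coif1_lo else coif1_hi, 1L)
    for (b2 in c("L", "H")) {
      s2 <- swt_axis(s1, if (b2 == "L") coif1_lo else coif1_hi, 2L)
      for (b3 in c("L", "H")) {
        s3 <- swt_axis(s2, if (b3 == "L") coif1_lo else coif1_hi, 3L)
        out[[paste0("wavelet-", b1, b2, b3)]] <-
          image_volume(s3, volume$spacing, volume$origin)
      }
    }
  }
  names(out) <- sub("^wavelet-", "", names(out))
  out[c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")]
}
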