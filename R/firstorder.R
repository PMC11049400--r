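# Gray-level discretization and the 18 first-order intensity features.

#' Discretize intensities with a fixed bin width
#'
#' Gray level \code{floor((x - min(x)) / bin_width) + 1}, anchoring the
#' first bin at the ROI minimum. Used both for the first-order histogram
#' features (entropy, uniformity) and as input to all texture matrices.
#'
#' @param values numeric vector of masked intensities.
#' @param bin_width bin width in intensity units (> 0).
#' @return Integer vector of gray levels (1-based).
#' @export
discretize <- function(values, bin_width) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  as.integer(floor((values - min(values)) / bin_width) + 1L)
}

quantile7 <- function(x, p) unname(stats::quantile(x, p, type = 7))

#' First-order intensity features
#'
#' The 18 standard first-order features. The energy family (Energy,
#' TotalEnergy, RMS) uses \code{value + shift} so that negative CT numbers
#' are not squared into ambiguity; Entropy and Uniformity are computed on
#' the fixed-bin-width histogram; Skewness and Kurtosis use population
#' moments (Kurtosis is not excess-corrected); robust MAD uses the
#' 10th-90th percentile subset. Degenerate inputs (zero variance) yield
#' defined fallbacks (0 for Skewness/Kurtosis) and are listed in the
#' \code{"flagged"} attribute.
#'
#' @param values numeric vector of masked intensities (length >= 1).
#' @param bin_width histogram bin width for Entropy/Uniformity.
#' @param shift offset added to intensities in the energy family.
#' @param voxel_volume physical voxel volume (mm^3) for TotalEnergy.
#' @return Named numeric vector of 18 features with a \code{"flagged"}
#'   character attribute naming degenerate entries.
#' @export
first_order_features <- function(values, bin_width = 25, shift = 0,
                                 voxel_volume = 1) {
  x <- as.numeric(values)
  n <- length(x)
  flagged <- character(0)
  xs <- x + shift
  energy <- sum(xs^2)

  levels <- discretize(x, bin_width)
  p <- tabulate(levels) / n
  p <- p[p > 0]

  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  if (m2 > 0) {
    skew <- m3 / m2^1.5
    kurt <- m4 / m2^2
  } else {
    skew <- 0; kurt <- 0
    flagged <- c(flagged, "Skewness", "Kurtosis")
  }

  p10 <- quantile7(x, 0.10); p90 <- quantile7(x, 0.90)
  mid <- x[x >= p10 & x <= p90]
  rmad <- if (length(mid) > 0) mean(abs(mid - mean(mid))) else 0

  out <- c(
    Energy = energy,
    TotalEnergy = voxel_volume * energy,
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    `10Percentile` = p10,
    `90Percentile` = p90,
    Maximum = max(x),
    Mean = mu,
    Median = stats::median(x),
    InterquartileRange = quantile7(x, 0.75) - quantile7(x, 0.25),
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = rmad,
    RootMeanSquared = sqrt(mean(xs^2)),
    Skewness = skew,
    Kurtosis = kurt,
    Variance = m2,
    Uniformity = sum(p^2)
  )
  attr(out, "flagged") <- flagged
  out
}
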