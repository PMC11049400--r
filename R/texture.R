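# Texture matrices over discretized gray levels: co-occurrence (GLCM),
# run length (GLRLM), size zone (GLSZM) and dependence (GLDM), with the
# standard feature formulas. Matrices are built over the gray levels
# actually present in the ROI (empty levels dropped); GLCM and GLRLM are
# computed per direction over the 13 unique 3D offsets at distance 1 and
# feature values averaged over directions; GLSZM zones and GLDM
# dependencies use 26-connectivity with dependence threshold 0 (equal
# levels only).

# The 13 unique direction offsets of the 26-neighborhood (one per +/- pair).
offsets_13 <- matrix(c(
  1, 0, 0,   0, 1, 0,   0, 0, 1,
  1, 1, 0,   1, -1, 0,  1, 0, 1,
  1, 0, -1,  0, 1, 1,   0, 1, -1,
  1, 1, 1,   1, 1, -1,  1, -1, 1,
  1, -1, -1), ncol = 3, byrow = TRUE)

# Index ranges of the overlapping slabs for an offset d: voxel a at
# position p pairs with voxel b at p + d.
offset_ranges <- function(dims, d) {
  a <- vector("list", 3L); b <- vector("list", 3L)
  for (ax in 1:3) {
    lo <- max(1L, 1L - d[ax]); hi <- min(dims[ax], dims[ax] - d[ax])
    if (lo > hi) return(NULL)
    a[[ax]] <- lo:hi
    b[[ax]] <- (lo + d[ax]):(hi + d[ax])
  }
  list(a = a, b = b)
}

sub3 <- function(arr, idx) arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]

# Rank array: map gray levels inside the mask to ranks 1..Ng over present
# levels; returns the rank array (NA outside mask) and the level values.
rank_levels <- function(levels_arr, mask) {
  lv <- levels_arr[mask]
  present <- sort(unique(lv))
  rk <- array(NA_integer_, dim = dim(levels_arr))
  rk[mask] <- match(levels_arr[mask], present)
  list(rank = rk, gl = as.numeric(present), ng = length(present),
       np = sum(mask))
}

entropy2 <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }

## ---------------------------------------------------------------- GLCM --

glcm_matrix_direction <- function(rk, d, ng) {
  r <- offset_ranges(dim(rk), d)
  if (is.null(r)) return(matrix(0, ng, ng))
  a <- sub3(rk, r$a); b <- sub3(rk, r$b)
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(matrix(0, ng, ng))
  counts <- tabulate((a[ok] - 1L) * ng + b[ok], nbins = ng * ng)
  C <- matrix(counts, ng, ng, byrow = TRUE)
  C + t(C)  # symmetric
}

glcm_features_from_p <- function(p, gl) {
  ng <- length(gl)
  I <- matrix(gl, ng, ng)
  J <- t(I)
  px <- rowSums(p)                       # symmetric: py = px
  mu <- sum(gl * px)
  sigma2 <- sum((gl - mu)^2 * px)

  dif <- abs(I - J)
  pd <- tapply(p, dif, sum)
  dk <- as.numeric(names(pd))
  da <- sum(dk * pd)

  sm <- I + J
  ps <- tapply(p, sm, sum)

  hx <- entropy2(px)
  hxy <- entropy2(p)
  pp <- p > 0
  pxpy <- outer(px, px)
  hxy1 <- -sum(p[pp] * log2(pxpy[pp]))
  qq <- pxpy > 0
  hxy2 <- -sum(pxpy[qq] * log2(pxpy[qq]))

  imc1 <- if (max(hx, hx) > 0) (hxy - hxy1) / hx else 0
  imc2 <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0

  corr <- if (sigma2 > 0) (sum(I * J * p) - mu^2) / sigma2 else 1

  offdiag <- dif > 0
  c(
    Autocorrelation = sum(I * J * p),
    ClusterProminence = sum((I + J - 2 * mu)^4 * p),
    ClusterShade = sum((I + J - 2 * mu)^3 * p),
    ClusterTendency = sum((I + J - 2 * mu)^2 * p),
    Contrast = sum((I - J)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = entropy2(pd),
    DifferenceVariance = sum((dk - da)^2 * pd),
    Id = sum(p / (1 + dif)),
    Idm = sum(p / (1 + dif^2)),
    Idmn = sum(p / (1 + (dif / ng)^2)),
    Idn = sum(p / (1 + dif / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(p[offdiag] / dif[offdiag]^2),
    JointAverage = mu,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MaximumProbability = max(p),
    SumEntropy = entropy2(ps),
    SumSquares = sum((I - mu)^2 * p)
  )
}

#' Gray-level co-occurrence features
#'
#' Symmetric co-occurrence over the 13 unique 3D directions at distance 1,
#' normalized per direction, with the 22 feature values averaged over the
#' directions that contain at least one voxel pair. A single-voxel ROI has
#' no pairs: all features come back NA and flagged. A single-gray-level
#' ROI leaves Correlation undefined; the defined fallback is 1 (perfect
#' association), flagged.
#'
#' @param levels_arr integer 3D array of discretized gray levels.
#' @param mask logical 3D array, same shape.
#' @return Named numeric vector of 22 features with a \code{"flagged"}
#'   attribute.
#' @export
glcm_features <- function(levels_arr, mask) {
  ri <- rank_levels(levels_arr, mask)
  flagged <- character(0)
  per_dir <- list()
  for (k in seq_len(nrow(offsets_13))) {
    P <- glcm_matrix_direction(ri$rank, offsets_13[k, ], ri$ng)
    s <- sum(P)
    if (s == 0) next
    per_dir[[length(per_dir) + 1L]] <- glcm_features_from_p(P / s, ri$gl)
  }
  if (length(per_dir) == 0L) {
    out <- rep(NA_real_, 22)
    names(out) <- names(glcm_features_from_p(matrix(1), 1))
    attr(out, "flagged") <- names(out)
    return(out)
  }
  out <- colMeans(do.call(rbind, per_dir))
  if (ri$ng == 1L) flagged <- c(flagged, "Correlation")
  attr(out, "flagged") <- flagged
  out
}

## --------------------------------------------------------------- GLRLM --

# All runs along direction d: levels of consecutive in-mask voxels.
# Returns a two-column matrix (gray rank, run length). `coord` is the full
# grid coordinate matrix, precomputed once per array by the caller.
runs_direction <- function(rk, d, coord = NULL) {
  dims <- dim(rk)
  n1 <- dims[1]; n12 <- dims[1] * dims[2]
  if (is.null(coord))
    coord <- as.matrix(expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                                   k = seq_len(dims[3])))
  # line start voxels: predecessors p - d fall outside the grid
  prev <- sweep(coord, 2, d, "-")
  is_start <- prev[, 1] < 1 | prev[, 1] > dims[1] |
              prev[, 2] < 1 | prev[, 2] > dims[2] |
              prev[, 3] < 1 | prev[, 3] > dims[3]
  starts <- coord[is_start, , drop = FALSE]
  lmax <- max(dims)
  vals <- matrix(NA_integer_, nrow = nrow(starts), ncol = lmax + 1L)
  for (t in seq_len(lmax)) {
    pos <- sweep(starts, 2, (t - 1L) * d, "+")
    ok <- pos[, 1] >= 1 & pos[, 1] <= dims[1] &
          pos[, 2] >= 1 & pos[, 2] <= dims[2] &
          pos[, 3] >= 1 & pos[, 3] <= dims[3]
    if (!any(ok)) break
    lin <- pos[ok, 1] + (pos[ok, 2] - 1L) * n1 + (pos[ok, 3] - 1L) * n12
    vals[ok, t] <- rk[lin]
  }
  seqv <- as.vector(t(vals))     # rows separated by the trailing NA column
  r <- rle(seqv)
  keep <- !is.na(r$values)
  cbind(rank = r$values[keep], len = r$lengths[keep])
}

rl_features_from_P <- function(P, gl, np, prefix) {
  nr <- sum(P)
  p <- P / nr
  ng <- nrow(P); lmax <- ncol(P)
  iv <- matrix(gl, ng, lmax)
  jv <- matrix(seq_len(lmax), ng, lmax, byrow = TRUE)
  mu_i <- sum(p * iv); mu_j <- sum(p * jv)
  short <- if (prefix == "Run") "ShortRun" else "SmallArea"
  long <- if (prefix == "Run") "LongRun" else "LargeArea"
  sizeword <- if (prefix == "Run") "RunLength" else "SizeZone"
  lvl <- if (prefix == "Run") "Run" else "Zone"
  out <- c(
    sum(P / jv^2) / nr,
    sum(P * jv^2) / nr,
    sum(rowSums(P)^2) / nr,
    sum(rowSums(P)^2) / nr^2,
    sum(colSums(P)^2) / nr,
    sum(colSums(P)^2) / nr^2,
    nr / np,
    sum(p * (iv - mu_i)^2),
    sum(p * (jv - mu_j)^2),
    entropy2(p),
    sum(P / iv^2) / nr,
    sum(P * iv^2) / nr,
    sum(P / (iv^2 * jv^2)) / nr,
    sum(P * iv^2 / jv^2) / nr,
    sum(P * jv^2 / iv^2) / nr,
    sum(P * iv^2 * jv^2) / nr
  )
  names(out) <- c(
    paste0(short, "Emphasis"),
    paste0(long, "Emphasis"),
    "GrayLevelNonUniformity",
    "GrayLevelNonUniformityNormalized",
    paste0(sizeword, "NonUniformity"),
    paste0(sizeword, "NonUniformityNormalized"),
    paste0(lvl, "Percentage"),
    "GrayLevelVariance",
    paste0(lvl, "Variance"),
    paste0(lvl, "Entropy"),
    paste0("LowGrayLevel", lvl, "Emphasis"),
    paste0("HighGrayLevel", lvl, "Emphasis"),
    paste0(short, "LowGrayLevelEmphasis"),
    paste0(short, "HighGrayLevelEmphasis"),
    paste0(long, "LowGrayLevelEmphasis"),
    paste0(long, "HighGrayLevelEmphasis")
  )
  out
}

#' Gray-level run-length features
#'
#' Runs of equal gray level along each of the 13 unique 3D directions;
#' the 16 features are computed per direction and averaged.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features with a \code{"flagged"}
#'   attribute.
#' @export
glrlm_features <- function(levels_arr, mask) {
  ri <- rank_levels(levels_arr, mask)
  lmax <- max(dim(levels_arr))
  dims <- dim(levels_arr)
  coord <- as.matrix(expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                                 k = seq_len(dims[3])))
  per_dir <- list()
  for (k in seq_len(nrow(offsets_13))) {
    rl <- runs_direction(ri$rank, offsets_13[k, ], coord)
    if (nrow(rl) == 0L) next
    P <- matrix(0, ri$ng, lmax)
    tab <- tabulate((rl[, "rank"] - 1L) * lmax + rl[, "len"], nbins = ri$ng * lmax)
    P <- matrix(tab, ri$ng, lmax, byrow = TRUE)
    per_dir[[length(per_dir) + 1L]] <- rl_features_from_P(P, ri$gl, ri$np, "Run")
  }
  out <- colMeans(do.call(rbind, per_dir))
  attr(out, "flagged") <- character(0)
  out
}

## --------------------------------------------------------------- GLSZM --

# Label 26-connected iso-intensity zones by iterative minimum-label
# propagation; returns an array of zone labels (NA outside the mask).
label_zones <- function(rk) {
  lab <- array(NA_real_, dim = dim(rk))
  inmask <- !is.na(rk)
  lab[inmask] <- seq_len(sum(inmask))
  dims <- dim(rk)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(offsets_13))) {
      r <- offset_ranges(dims, offsets_13[k, ])
      if (is.null(r)) next
      la <- sub3(lab, r$a); lb <- sub3(lab, r$b)
      va <- sub3(rk, r$a);  vb <- sub3(rk, r$b)
      same <- !is.na(va) & !is.na(vb) & va == vb
      upd_a <- same & lb < la
      if (any(upd_a, na.rm = TRUE)) {
        la[which(upd_a)] <- lb[which(upd_a)]
        lab[r$a[[1]], r$a[[2]], r$a[[3]]] <- la
        changed <- TRUE
        la <- sub3(lab, r$a)
      }
      upd_b <- same & la < lb
      if (any(upd_b, na.rm = TRUE)) {
        lb[which(upd_b)] <- la[which(upd_b)]
        lab[r$b[[1]], r$b[[2]], r$b[[3]]] <- lb
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

#' Gray-level size-zone features
#'
#' 26-connected zones of equal gray level; a constant ROI is one zone
#' covering every voxel. 16 features, single (direction-free) matrix.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features with a \code{"flagged"}
#'   attribute.
#' @export
glszm_features <- function(levels_arr, mask) {
  ri <- rank_levels(levels_arr, mask)
  lab <- label_zones(ri$rank)
  zl <- lab[mask]
  rk <- ri$rank[mask]
  zone_size <- table(zl)
  zone_rank <- rk[match(as.numeric(names(zone_size)), zl)]
  smax <- max(as.integer(zone_size))
  tab <- tabulate((zone_rank - 1L) * smax + as.integer(zone_size),
                  nbins = ri$ng * smax)
  P <- matrix(tab, ri$ng, smax, byrow = TRUE)
  out <- rl_features_from_P(P, ri$gl, ri$np, "Zone")
  attr(out, "flagged") <- character(0)
  out
}

## ---------------------------------------------------------------- GLDM --

#' Gray-level dependence features
#'
#' For every in-mask voxel, the dependence is 1 plus the number of its
#' 26-neighbors inside the mask with the same gray level (dependence
#' threshold alpha = 0). 14 features from the (gray level, dependence)
#' matrix.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 14 features with a \code{"flagged"}
#'   attribute.
#' @export
gldm_features <- function(levels_arr, mask) {
  ri <- rank_levels(levels_arr, mask)
  rk <- ri$rank
  dims <- dim(rk)
  dep <- array(0L, dim = dims)
  for (k in seq_len(nrow(offsets_13))) {
    for (sgn in c(1L, -1L)) {
      d <- sgn * offsets_13[k, ]
      r <- offset_ranges(dims, d)
      if (is.null(r)) next
      va <- sub3(rk, r$a); vb <- sub3(rk, r$b)
      hit <- !is.na(va) & !is.na(vb) & va == vb
      da <- sub3(dep, r$a)
      da[hit] <- da[hit] + 1L
      dep[r$a[[1]], r$a[[2]], r$a[[3]]] <- da
    }
  }
  dvals <- dep[mask] + 1L   # dependence includes the center voxel
  rks <- rk[mask]
  dmax <- max(dvals)
  tab <- tabulate((rks - 1L) * dmax + dvals, nbins = ri$ng * dmax)
  P <- matrix(tab, ri$ng, dmax, byrow = TRUE)
  nz <- sum(P)   # == number of voxels
  p <- P / nz
  iv <- matrix(ri$gl, ri$ng, dmax)
  jv <- matrix(seq_len(dmax), ri$ng, dmax, byrow = TRUE)
  mu_i <- sum(p * iv); mu_j <- sum(p * jv)
  out <- c(
    SmallDependenceEmphasis = sum(P / jv^2) / nz,
    LargeDependenceEmphasis = sum(P * jv^2) / nz,
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nz,
    DependenceNonUniformity = sum(colSums(P)^2) / nz,
    DependenceNonUniformityNormalized = sum(colSums(P)^2) / nz^2,
    GrayLevelVariance = sum(p * (iv - mu_i)^2),
    DependenceVariance = sum(p * (jv - mu_j)^2),
    DependenceEntropy = entropy2(p),
    LowGrayLevelEmphasis = sum(P / iv^2) / nz,
    HighGrayLevelEmphasis = sum(P * iv^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P / (iv^2 * jv^2)) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * iv^2 / jv^2) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * jv^2 / iv^2) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * iv^2 * jv^2) / nz
  )
  attr(out, "flagged") <- character(0)
  out
}
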