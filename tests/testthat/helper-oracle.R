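# Brute-force reference implementations of the texture feature classes,
# written as direct scalar-loop transcriptions of the matrix definitions
# and feature formulas. They share the package's conventions (gray levels
# present in the ROI, 13-direction averaging, dependence includes the
# center voxel) but none of its code paths, and serve as the independent
# oracle for feature equivalence checks.

oracle_dirs <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

oracle_in_grid <- function(p, dims) {
  all(p >= 1) && p[1] <= dims[1] && p[2] <= dims[2] && p[3] <= dims[3]
}

oracle_mask_coords <- function(mask) which(mask, arr.ind = TRUE)

oracle_entropy <- function(p) {
  s <- 0
  for (v in p) if (v > 0) s <- s - v * log2(v)
  s
}

## GLCM ------------------------------------------------------------------

oracle_glcm_dir <- function(lv, mask, d, present) {
  ng <- length(present)
  C <- matrix(0, ng, ng)
  dims <- dim(lv)
  co <- oracle_mask_coords(mask)
  for (r in seq_len(nrow(co))) {
    p <- co[r, ]
    q <- p + d
    if (oracle_in_grid(q, dims) && mask[q[1], q[2], q[3]]) {
      i <- which(present == lv[p[1], p[2], p[3]])
      j <- which(present == lv[q[1], q[2], q[3]])
      C[i, j] <- C[i, j] + 1
      C[j, i] <- C[j, i] + 1
    }
  }
  C
}

oracle_glcm_feats <- function(p, gl) {
  ng <- length(gl)
  px <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) px[i] <- px[i] + p[i, j]
  mu <- 0; for (i in 1:ng) mu <- mu + gl[i] * px[i]
  sig2 <- 0; for (i in 1:ng) sig2 <- sig2 + (gl[i] - mu)^2 * px[i]

  # difference and sum distributions aggregated over gray-value difference
  dvals <- sort(unique(as.vector(abs(outer(gl, gl, "-")))))
  pd <- numeric(length(dvals))
  svals <- sort(unique(as.vector(outer(gl, gl, "+"))))
  ps <- numeric(length(svals))
  for (i in 1:ng) for (j in 1:ng) {
    pd[which(dvals == abs(gl[i] - gl[j]))] <-
      pd[which(dvals == abs(gl[i] - gl[j]))] + p[i, j]
    ps[which(svals == gl[i] + gl[j])] <-
      ps[which(svals == gl[i] + gl[j])] + p[i, j]
  }
  da <- 0; for (k in seq_along(dvals)) da <- da + dvals[k] * pd[k]
  dv <- 0; for (k in seq_along(dvals)) dv <- dv + (dvals[k] - da)^2 * pd[k]

  hx <- oracle_entropy(px)
  hxy <- oracle_entropy(as.vector(p))
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    pij <- px[i] * px[j]
    if (p[i, j] > 0 && pij > 0) hxy1 <- hxy1 - p[i, j] * log2(pij)
    if (pij > 0) hxy2 <- hxy2 - pij * log2(pij)
  }

  acc <- 0; cp <- 0; cs <- 0; ct <- 0; con <- 0; idf <- 0; idmf <- 0
  idmn <- 0; idn <- 0; iv <- 0; je <- 0; mp <- 0; ss <- 0; corr_num <- 0
  for (i in 1:ng) for (j in 1:ng) {
    pij <- p[i, j]; gi <- gl[i]; gj <- gl[j]; dd <- abs(gi - gj)
    acc <- acc + gi * gj * pij
    cp <- cp + (gi + gj - 2 * mu)^4 * pij
    cs <- cs + (gi + gj - 2 * mu)^3 * pij
    ct <- ct + (gi + gj - 2 * mu)^2 * pij
    con <- con + (gi - gj)^2 * pij
    idf <- idf + pij / (1 + dd)
    idmf <- idmf + pij / (1 + dd^2)
    idmn <- idmn + pij / (1 + (dd / ng)^2)
    idn <- idn + pij / (1 + dd / ng)
    if (dd > 0) iv <- iv + pij / dd^2
    je <- je + pij^2
    if (pij > mp) mp <- pij
    ss <- ss + (gi - mu)^2 * pij
    corr_num <- corr_num + gi * gj * pij
  }
  corr <- if (sig2 > 0) (corr_num - mu^2) / sig2 else 1
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0

  c(Autocorrelation = acc, ClusterProminence = cp, ClusterShade = cs,
    ClusterTendency = ct, Contrast = con, Correlation = corr,
    DifferenceAverage = da, DifferenceEntropy = oracle_entropy(pd),
    DifferenceVariance = dv, Id = idf, Idm = idmf, Idmn = idmn, Idn = idn,
    Imc1 = imc1, Imc2 = imc2, InverseVariance = iv, JointAverage = mu,
    JointEnergy = je, JointEntropy = hxy, MaximumProbability = mp,
    SumEntropy = oracle_entropy(ps), SumSquares = ss)
}

oracle_glcm <- function(lv, mask) {
  present <- sort(unique(lv[mask]))
  acc <- NULL
  for (k in seq_len(nrow(oracle_dirs))) {
    C <- oracle_glcm_dir(lv, mask, oracle_dirs[k, ], present)
    if (sum(C) == 0) next
    acc <- rbind(acc, oracle_glcm_feats(C / sum(C), as.numeric(present)))
  }
  colMeans(acc)
}

## GLRLM -----------------------------------------------------------------

oracle_runs_dir <- function(lv, mask, d) {
  dims <- dim(lv)
  runs <- list()
  co <- which(array(TRUE, dims), arr.ind = TRUE)
  for (r in seq_len(nrow(co))) {
    p <- co[r, ]
    if (!mask[p[1], p[2], p[3]]) next
    val <- lv[p[1], p[2], p[3]]
    prev <- p - d
    starts_run <- !oracle_in_grid(prev, dims) ||
      !mask[prev[1], prev[2], prev[3]] ||
      lv[prev[1], prev[2], prev[3]] != val
    if (!starts_run) next
    len <- 1
    q <- p + d
    while (oracle_in_grid(q, dims) && mask[q[1], q[2], q[3]] &&
           lv[q[1], q[2], q[3]] == val) {
      len <- len + 1
      q <- q + d
    }
    runs[[length(runs) + 1]] <- c(val, len)
  }
  do.call(rbind, runs)
}

oracle_sizezone_feats <- function(P, gl, np, kind) {
  nr <- sum(P)
  ng <- nrow(P); lmax <- ncol(P)
  sre <- 0; lre <- 0; gln <- 0; rln <- 0; glv <- 0; rv <- 0
  lgl <- 0; hgl <- 0; srl <- 0; srh <- 0; lrl <- 0; lrh <- 0
  mu_i <- 0; mu_j <- 0
  for (i in 1:ng) for (j in 1:lmax) {
    mu_i <- mu_i + P[i, j] / nr * gl[i]
    mu_j <- mu_j + P[i, j] / nr * j
  }
  for (i in 1:ng) for (j in 1:lmax) {
    v <- P[i, j]
    sre <- sre + v / j^2; lre <- lre + v * j^2
    glv <- glv + v / nr * (gl[i] - mu_i)^2
    rv <- rv + v / nr * (j - mu_j)^2
    lgl <- lgl + v / gl[i]^2; hgl <- hgl + v * gl[i]^2
    srl <- srl + v / (gl[i]^2 * j^2); srh <- srh + v * gl[i]^2 / j^2
    lrl <- lrl + v * j^2 / gl[i]^2; lrh <- lrh + v * gl[i]^2 * j^2
  }
  for (i in 1:ng) gln <- gln + sum(P[i, ])^2
  for (j in 1:lmax) rln <- rln + sum(P[, j])^2
  short <- if (kind == "Run") "ShortRun" else "SmallArea"
  long <- if (kind == "Run") "LongRun" else "LargeArea"
  sizeword <- if (kind == "Run") "RunLength" else "SizeZone"
  out <- c(sre / nr, lre / nr, gln / nr, gln / nr^2, rln / nr, rln / nr^2,
           nr / np, glv, rv, oracle_entropy(as.vector(P / nr)),
           lgl / nr, hgl / nr, srl / nr, srh / nr, lrl / nr, lrh / nr)
  names(out) <- c(paste0(short, "Emphasis"), paste0(long, "Emphasis"),
                  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                  paste0(sizeword, "NonUniformity"),
                  paste0(sizeword, "NonUniformityNormalized"),
                  paste0(kind, "Percentage"), "GrayLevelVariance",
                  paste0(kind, "Variance"), paste0(kind, "Entropy"),
                  paste0("LowGrayLevel", kind, "Emphasis"),
                  paste0("HighGrayLevel", kind, "Emphasis"),
                  paste0(short, "LowGrayLevelEmphasis"),
                  paste0(short, "HighGrayLevelEmphasis"),
                  paste0(long, "LowGrayLevelEmphasis"),
                  paste0(long, "HighGrayLevelEmphasis"))
  out
}

oracle_glrlm <- function(lv, mask) {
  present <- sort(unique(lv[mask]))
  np <- sum(mask)
  lmax <- max(dim(lv))
  acc <- NULL
  for (k in seq_len(nrow(oracle_dirs))) {
    runs <- oracle_runs_dir(lv, mask, oracle_dirs[k, ])
    if (is.null(runs)) next
    P <- matrix(0, length(present), lmax)
    for (r in seq_len(nrow(runs))) {
      i <- which(present == runs[r, 1])
      P[i, runs[r, 2]] <- P[i, runs[r, 2]] + 1
    }
    acc <- rbind(acc, oracle_sizezone_feats(P, as.numeric(present), np, "Run"))
  }
  colMeans(acc)
}

## GLSZM -----------------------------------------------------------------

oracle_all26 <- rbind(oracle_dirs, -oracle_dirs)

oracle_glszm <- function(lv, mask) {
  present <- sort(unique(lv[mask]))
  dims <- dim(lv)
  seen <- array(FALSE, dims)
  zones <- list()
  co <- oracle_mask_coords(mask)
  for (r in seq_len(nrow(co))) {
    p <- co[r, ]
    if (seen[p[1], p[2], p[3]]) next
    val <- lv[p[1], p[2], p[3]]
    stack <- list(p); seen[p[1], p[2], p[3]] <- TRUE; size <- 0
    while (length(stack) > 0) {
      q <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1
      for (n in seq_len(nrow(oracle_all26))) {
        w <- q + oracle_all26[n, ]
        if (oracle_in_grid(w, dims) && mask[w[1], w[2], w[3]] &&
            !seen[w[1], w[2], w[3]] && lv[w[1], w[2], w[3]] == val) {
          seen[w[1], w[2], w[3]] <- TRUE
          stack[[length(stack) + 1]] <- w
        }
      }
    }
    zones[[length(zones) + 1]] <- c(val, size)
  }
  zm <- do.call(rbind, zones)
  smax <- max(zm[, 2])
  P <- matrix(0, length(present), smax)
  for (r in seq_len(nrow(zm))) {
    i <- which(present == zm[r, 1])
    P[i, zm[r, 2]] <- P[i, zm[r, 2]] + 1
  }
  oracle_sizezone_feats(P, as.numeric(present), sum(mask), "Zone")
}

## GLDM ------------------------------------------------------------------

oracle_gldm <- function(lv, mask) {
  present <- sort(unique(lv[mask]))
  dims <- dim(lv)
  co <- oracle_mask_coords(mask)
  deps <- integer(nrow(co)); vals <- integer(nrow(co))
  for (r in seq_len(nrow(co))) {
    p <- co[r, ]
    val <- lv[p[1], p[2], p[3]]
    cnt <- 0
    for (n in seq_len(nrow(oracle_all26))) {
      q <- p + oracle_all26[n, ]
      if (oracle_in_grid(q, dims) && mask[q[1], q[2], q[3]] &&
          lv[q[1], q[2], q[3]] == val) cnt <- cnt + 1
    }
    deps[r] <- cnt + 1   # dependence includes the center voxel
    vals[r] <- val
  }
  dmax <- max(deps); ng <- length(present); nz <- length(deps)
  P <- matrix(0, ng, dmax)
  for (r in seq_along(deps))
    P[which(present == vals[r]), deps[r]] <- P[which(present == vals[r]), deps[r]] + 1
  gl <- as.numeric(present)
  mu_i <- 0; mu_j <- 0
  for (i in 1:ng) for (j in 1:dmax) {
    mu_i <- mu_i + P[i, j] / nz * gl[i]
    mu_j <- mu_j + P[i, j] / nz * j
  }
  sde <- 0; lde <- 0; glv <- 0; dv <- 0; lgl <- 0; hgl <- 0
  sdl <- 0; sdh <- 0; ldl <- 0; ldh <- 0; gln <- 0; dn <- 0
  for (i in 1:ng) for (j in 1:dmax) {
    v <- P[i, j]
    sde <- sde + v / j^2; lde <- lde + v * j^2
    glv <- glv + v / nz * (gl[i] - mu_i)^2
    dv <- dv + v / nz * (j - mu_j)^2
    lgl <- lgl + v / gl[i]^2; hgl <- hgl + v * gl[i]^2
    sdl <- sdl + v / (gl[i]^2 * j^2); sdh <- sdh + v * gl[i]^2 / j^2
    ldl <- ldl + v * j^2 / gl[i]^2; ldh <- ldh + v * gl[i]^2 * j^2
  }
  for (i in 1:ng) gln <- gln + sum(P[i, ])^2
  for (j in 1:dmax) dn <- dn + sum(P[, j])^2
  c(SmallDependenceEmphasis = sde / nz, LargeDependenceEmphasis = lde / nz,
    GrayLevelNonUniformity = gln / nz, DependenceNonUniformity = dn / nz,
    DependenceNonUniformityNormalized = dn / nz^2, GrayLevelVariance = glv,
    DependenceVariance = dv,
    DependenceEntropy = oracle_entropy(as.vector(P / nz)),
    LowGrayLevelEmphasis = lgl / nz, HighGrayLevelEmphasis = hgl / nz,
    SmallDependenceLowGrayLevelEmphasis = sdl / nz,
    SmallDependenceHighGrayLevelEmphasis = sdh / nz,
    LargeDependenceLowGrayLevelEmphasis = ldl / nz,
    LargeDependenceHighGrayLevelEmphasis = ldh / nz)
}

## First order ----------------------------------------------------------

oracle_firstorder <- function(x, bin_width, shift, voxel_volume) {
  n <- length(x)
  xs <- x + shift
  lev <- floor((x - min(x)) / bin_width) + 1
  counts <- table(lev)
  p <- as.numeric(counts) / n
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  p10 <- as.numeric(quantile(x, 0.1, type = 7))
  p90 <- as.numeric(quantile(x, 0.9, type = 7))
  mid <- x[x >= p10 & x <= p90]
  c(Energy = sum(xs^2),
    TotalEnergy = voxel_volume * sum(xs^2),
    Entropy = oracle_entropy(p),
    Minimum = min(x), `10Percentile` = p10, `90Percentile` = p90,
    Maximum = max(x), Mean = mu, Median = as.numeric(quantile(x, 0.5, type = 7)),
    InterquartileRange = as.numeric(quantile(x, .75, type = 7) - quantile(x, .25, type = 7)),
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = sum(abs(x - mu)) / n,
    RobustMeanAbsoluteDeviation = sum(abs(mid - mean(mid))) / length(mid),
    RootMeanSquared = sqrt(sum(xs^2) / n),
    Skewness = if (m2 > 0) (sum((x - mu)^3) / n) / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) (sum((x - mu)^4) / n) / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
}

# Random small discretized ROI for oracle comparisons.
random_level_roi <- function(dims = c(4, 4, 4), n_levels = 5,
                             mask_density = 0.75) {
  lv <- array(sample.int(n_levels, prod(dims), replace = TRUE), dim = dims)
  mask <- array(runif(prod(dims)) < mask_density, dim = dims)
  if (sum(mask) < 2) mask[1:2] <- TRUE
  list(lv = lv, mask = mask)
}
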