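# Per-feature screen for temporal dependence across the seven contrast
# phases: linear mixed models with a random patient intercept (optionally
# plus a visit intercept), Satterthwaite-approximated p-values for the
# timepoint effect, Benjamini-Hochberg FDR, z-scored mean profiles and
# complete-linkage clustering of the significant features.

#' Statistics configuration
#'
#' @param alpha significance level for the joint p/FDR rule (default 0.05).
#' @param timepoint_coding \code{"numeric"} (default; phase index 1-7
#'   enters as a single fixed covariate) or \code{"categorical"} (joint
#'   F-test over phase factor levels).
#' @param formula_variant \code{"patient"} (random patient intercept) or
#'   \code{"patient_visit"} (adds a random visit intercept for designs
#'   with repeated visits).
#' @return A \code{stats_config} object.
#' @export
stats_config <- function(alpha = 0.05,
                         timepoint_coding = c("numeric", "categorical"),
                         formula_variant = c("patient", "patient_visit")) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  structure(list(alpha = alpha,
                 timepoint_coding = match.arg(timepoint_coding),
                 formula_variant = match.arg(formula_variant)),
            class = "stats_config")
}

#' Fit the mixed model for one feature
#'
#' REML fit of \code{value ~ phase + (1 | subject)} (plus
#' \code{(1 | visit)} when configured), with the p-value for the timepoint
#' effect from the Satterthwaite degrees-of-freedom approximation.
#' Zero-variance features and fits that fail are excluded, mirroring how
#' non-converging features are dropped from the screen.
#'
#' @param df data.frame with columns \code{subject}, \code{phase},
#'   \code{value} (and \code{visit} for the visit variant); rows for one
#'   feature in one ROI. Flagged values should be set to NA beforehand.
#' @param cfg a [stats_config()].
#' @return List: \code{estimate} (fixed timepoint effect; NA for the
#'   categorical coding), \code{p}, \code{converged}, \code{excluded}.
#' @export
fit_lmm <- function(df, cfg = stats_config()) {
  df <- df[is.finite(df$value), , drop = FALSE]
  res <- list(estimate = NA_real_, p = NA_real_, converged = FALSE,
              excluded = TRUE)
  if (nrow(df) == 0L || length(unique(df$subject)) < 2L ||
      length(unique(df$phase)) < 2L)
    return(res)
  if (stats::var(df$value) == 0) return(res)
  df$phase_num <- as.numeric(df$phase)
  df$phase_cat <- factor(df$phase)
  form <- if (cfg$timepoint_coding == "numeric")
    value ~ phase_num + (1 | subject) else value ~ phase_cat + (1 | subject)
  if (cfg$formula_variant == "patient_visit") {
    if (is.null(df$visit)) stop("visit column required for the patient_visit variant")
    form <- stats::update.formula(form, . ~ . + (1 | visit))
  }
  fit <- tryCatch(
    suppressMessages(suppressWarnings(lmerTest::lmer(form, data = df))),
    error = function(e) NULL)
  if (is.null(fit)) return(res)
  out <- tryCatch({
    if (cfg$timepoint_coding == "numeric") {
      ct <- stats::coef(summary(fit))
      list(estimate = unname(ct["phase_num", "Estimate"]),
           p = unname(ct["phase_num", "Pr(>|t|)"]),
           converged = TRUE, excluded = FALSE)
    } else {
      an <- stats::anova(fit)   # lmerTest: Satterthwaite type III
      list(estimate = NA_real_, p = unname(an[["Pr(>F)"]][1]),
           converged = TRUE, excluded = FALSE)
    }
  }, error = function(e) res)
  if (!is.finite(out$p)) return(res)
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone in rank, capped at 1).
#'
#' @param p numeric vector of p-values.
#' @return Adjusted q-values, same order as \code{p}.
#' @export
bh_fdr <- function(p) stats::p.adjust(p, method = "BH")

#' Screen every feature of one ROI for temporal dependence
#'
#' Fits the mixed model per feature, adjusts the converged p-values with
#' [bh_fdr()] (excluded features are not part of the FDR universe) and
#' applies the joint rule p < alpha AND q < alpha.
#'
#' @param table long feature table (see [cohort_feature_table()]),
#'   restricted to one ROI by \code{roi}.
#' @param roi ROI label to screen.
#' @param cfg a [stats_config()].
#' @return data.frame: feature, estimate, p, q, converged, excluded,
#'   significant.
#' @export
screen_features <- function(table, roi = "tumor", cfg = stats_config()) {
  tab <- table[table$roi == roi, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no rows for roi '", roi, "'")
  tab$value[tab$flag] <- NA_real_   # degenerate fallbacks treated as missing
  feats <- unique(tab$feature)
  fits <- vector("list", length(feats))
  idx <- split(seq_len(nrow(tab)), tab$feature)
  for (i in seq_along(feats)) {
    fits[[i]] <- fit_lmm(tab[idx[[feats[i]]], , drop = FALSE], cfg)
  }
  res <- data.frame(
    feature = feats,
    estimate = vapply(fits, `[[`, numeric(1), "estimate"),
    p = vapply(fits, `[[`, numeric(1), "p"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    excluded = vapply(fits, `[[`, logical(1), "excluded"),
    stringsAsFactors = FALSE)
  res$q <- NA_real_
  ok <- res$converged & !res$excluded
  res$q[ok] <- bh_fdr(res$p[ok])
  res$significant <- ok & res$p < cfg$alpha & res$q < cfg$alpha
  res$significant[is.na(res$significant)] <- FALSE
  res
}

#' Significant features under the joint p/FDR rule
#'
#' @param results data.frame from [screen_features()].
#' @param cfg a [stats_config()].
#' @return Character vector of feature names with converged fits,
#'   p < alpha and q < alpha.
#' @export
significant_features <- function(results, cfg = stats_config()) {
  ok <- results$converged & !results$excluded &
    !is.na(results$p) & !is.na(results$q) &
    results$p < cfg$alpha & results$q < cfg$alpha
  results$feature[ok]
}

#' Z-scored mean temporal profile of one feature
#'
#' Mean value over subjects at each of the seven phases, then z-scored
#' across the seven phase means (sample standard deviation). A constant
#' profile returns all zeros with attribute \code{"constant" = TRUE}.
#'
#' @param table long feature table restricted to one ROI.
#' @param feature feature name.
#' @return Numeric vector of 7 z-scores (named TP1..TP7).
#' @export
zscore_profile <- function(table, feature) {
  tab <- table[table$feature == feature, , drop = FALSE]
  if (nrow(tab) == 0L) stop("feature not found: ", feature)
  means <- tapply(tab$value, tab$phase, mean, na.rm = TRUE)
  means <- means[order(as.numeric(names(means)))]
  s <- stats::sd(means)
  if (is.na(s) || s == 0) {
    out <- rep(0, length(means))
    names(out) <- paste0("TP", names(means))
    attr(out, "constant") <- TRUE
    return(out)
  }
  out <- (means - mean(means)) / s
  out <- as.numeric(out)
  names(out) <- paste0("TP", seq_along(out))
  attr(out, "constant") <- FALSE
  out
}

#' Z-scored profile matrix for a set of features
#'
#' @param table long feature table restricted to one ROI.
#' @param features character vector of feature names.
#' @return Matrix, one row per feature, 7 columns TP1..TP7.
#' @export
profile_matrix <- function(table, features) {
  m <- t(vapply(features, function(f) as.numeric(zscore_profile(table, f)),
                numeric(7)))
  rownames(m) <- features
  colnames(m) <- paste0("TP", 1:7)
  m
}

#' Cluster temporal profiles
#'
#' Agglomerative clustering with complete linkage on Euclidean distances
#' between z-scored profiles. When \code{k} is NULL the cut height is
#' chosen at the largest relative gap between successive merge heights
#' (searched over 2..9 clusters).
#'
#' @param profiles matrix from [profile_matrix()].
#' @param k number of clusters, or NULL for automatic choice.
#' @return List: \code{cluster} (named integer vector), \code{k},
#'   \code{tree} (an \code{hclust} object).
#' @export
cluster_profiles <- function(profiles, k = NULL) {
  n <- nrow(profiles)
  if (n < 2L) {
    cl <- stats::setNames(rep(1L, n), rownames(profiles))
    return(list(cluster = cl, k = 1L, tree = NULL))
  }
  tree <- stats::hclust(stats::dist(profiles, method = "euclidean"),
                        method = "complete")
  if (is.null(k)) {
    h <- tree$height
    kmax <- min(9L, n - 1L)
    # merge m (from the top) splits the tree into m+1 clusters
    gaps <- vapply(seq_len(kmax - 1L), function(m) {
      top <- h[n - m]; nxt <- h[n - m - 1L]
      if (top <= 0) return(0)
      (top - nxt) / top
    }, numeric(1))
    k <- which.max(gaps) + 1L
  }
  k <- min(k, n)
  cl <- stats::cutree(tree, k = k)
  list(cluster = cl, k = as.integer(k), tree = tree)
}
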