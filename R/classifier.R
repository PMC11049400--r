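# Phase-wise healthy-vs-tumor classification: L2-penalized logistic
# regression (regularization strength C = 1, matching the
# penalized-likelihood objective min 0.5*||w||^2 + C * sum(logloss)),
# evaluated with leave-one-out cross-validation and summarized as ROC/AUC
# with confidence intervals per contrast phase.

#' Classifier configuration
#'
#' @param C inverse regularization strength (> 0); the ridge penalty
#'   weight passed to the solver is \code{1 / (n * C)}.
#' @param scale within-fold z-scaling of features (default FALSE: raw
#'   feature scales, as with a default logistic-regression setup).
#' @param ci_method \code{"delong"} (default) or \code{"bootstrap"} for
#'   the AUC confidence interval.
#' @param maxit Newton iteration cap (pinned for determinism).
#' @return A \code{classifier_config} object.
#' @export
classifier_config <- function(C = 1, scale = FALSE,
                              ci_method = c("delong", "bootstrap"),
                              maxit = 200L) {
  if (C <= 0) stop("C must be > 0")
  structure(list(C = C, scale = scale, ci_method = match.arg(ci_method),
                 maxit = maxit),
            class = "classifier_config")
}

log1pexp <- function(z) ifelse(z > 30, z, log1p(exp(z)))

# Fit the L2-penalized logistic objective
#   min_{w,b} 0.5 * ||w||^2 + C * sum_i log(1 + exp(-y~_i (x_i' w + b)))
# (intercept unpenalized) and return a prediction function. Because the
# optimal w lies in the row span of X, the problem is solved exactly in
# the dual parameterization w = X' a by damped Newton iteration over the
# (n + 1)-dimensional (a, b): robust for the p >> n feature matrices of
# radiomics cohorts, on their raw scales, with no restriction on fold
# class counts.
ridge_logistic <- function(X, y, cfg) {
  X <- as.matrix(X)
  n <- nrow(X)
  C <- cfg$C
  K <- tcrossprod(X)
  a <- rep(0, n)
  pbar <- min(max(mean(y), 1e-12), 1 - 1e-12)
  b <- log(pbar / (1 - pbar))
  yt <- 2 * y - 1
  obj <- function(a, b) {
    f <- as.numeric(K %*% a) + b
    0.5 * sum(a * (K %*% a)) + C * sum(log1pexp(-yt * f))
  }
  cur <- obj(a, b)
  for (it in seq_len(cfg$maxit)) {
    f <- as.numeric(K %*% a) + b
    p <- 1 / (1 + exp(-f))
    gf <- C * (p - y)
    grad <- c(as.numeric(K %*% (a + gf)), sum(gf))
    W <- pmax(p * (1 - p), 1e-12)
    KW <- K * rep(W, each = n)      # K %*% diag(W)
    H <- rbind(cbind(K + C * (KW %*% K), C * as.numeric(K %*% W)),
               c(C * as.numeric(W %*% K), C * sum(W)))
    ridge <- 1e-10 * mean(abs(diag(H))) + 1e-300
    step <- tryCatch(solve(H + diag(ridge, n + 1L), grad),
                     error = function(e) grad / (mean(abs(diag(H))) + 1))
    t_ls <- 1
    repeat {
      a2 <- a - t_ls * step[seq_len(n)]
      b2 <- b - t_ls * step[n + 1L]
      new <- obj(a2, b2)
      if (is.finite(new) && new <= cur) break
      t_ls <- t_ls / 2
      if (t_ls < 1e-12) { a2 <- a; b2 <- b; new <- cur; break }
    }
    done <- abs(cur - new) <= 1e-12 * (abs(cur) + 1e-12)
    a <- a2; b <- b2; cur <- new
    if (done) break
  }
  w <- as.numeric(crossprod(X, a))
  function(newx) {
    f <- as.numeric(as.matrix(newx) %*% w) + b
    1 / (1 + exp(-f))
  }
}

#' Leave-one-out class probabilities
#'
#' Each ROI is left out in turn; the classifier is trained on the
#' remaining ROIs and the tumor-class probability is predicted for the
#' held-out ROI. Missing feature values are imputed with the
#' training-fold median (never the fold being predicted); optional
#' within-fold z-scaling uses training-fold statistics only.
#'
#' @param X numeric matrix, one row per ROI, one column per feature.
#' @param labels vector coercible to 0/1 (1 = tumor).
#' @param cfg a [classifier_config()].
#' @return Numeric vector of out-of-fold tumor probabilities, one per row.
#' @export
loo_probabilities <- function(X, labels, cfg = classifier_config()) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) stop("single-class input: need both classes")
  if (min(table(y)) < 2L) stop("need at least 2 ROIs per class")
  n <- nrow(X)
  probs <- numeric(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    med <- apply(Xtr, 2, stats::median, na.rm = TRUE)
    med[!is.finite(med)] <- 0
    for (j in which(colSums(is.na(Xtr)) > 0))
      Xtr[is.na(Xtr[, j]), j] <- med[j]
    xte <- X[i, ]
    xte[is.na(xte)] <- med[is.na(xte)]
    if (isTRUE(cfg$scale)) {
      mu <- colMeans(Xtr); sdv <- apply(Xtr, 2, stats::sd)
      sdv[sdv == 0 | !is.finite(sdv)] <- 1
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
      xte <- (xte - mu) / sdv
    }
    predict_fun <- ridge_logistic(Xtr, y[-i], cfg)
    probs[i] <- predict_fun(matrix(xte, nrow = 1))
  }
  probs
}

#' ROC AUC with confidence interval
#'
#' AUC as the Mann-Whitney pair statistic (ties counted 1/2); the 95
#' percent confidence interval comes from the DeLong method by default
#' (bootstrap optional), clamped to [0, 1].
#'
#' @param probabilities predicted scores.
#' @param labels 0/1 class labels (1 = positive).
#' @param cfg a [classifier_config()].
#' @return List: \code{auc}, \code{ci_low}, \code{ci_high},
#'   \code{probabilities}.
#' @export
roc_auc <- function(probabilities, labels, cfg = classifier_config()) {
  y <- as.integer(labels)
  pos <- probabilities[y == 1]; neg <- probabilities[y == 0]
  if (length(pos) == 0 || length(neg) == 0) stop("need both classes")
  cmp <- outer(pos, neg, "-")
  auc <- (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / length(cmp)
  ci <- tryCatch({
    r <- suppressMessages(pROC::roc(response = y, predictor = probabilities,
                                    levels = c(0, 1), direction = "<",
                                    quiet = TRUE))
    if (cfg$ci_method == "delong")
      as.numeric(suppressWarnings(pROC::ci.auc(r, method = "delong")))
    else
      as.numeric(suppressWarnings(pROC::ci.auc(r, method = "bootstrap",
                                               boot.n = 2000,
                                               progress = "none")))
  }, error = function(e) c(NA_real_, auc, NA_real_))
  list(auc = auc,
       ci_low = max(0, min(ci[1], auc, na.rm = TRUE)),
       ci_high = min(1, max(ci[3], auc, na.rm = TRUE)),
       probabilities = probabilities)
}

# Wide matrix (ROIs x features) for one phase of the long table.
phase_matrix <- function(table, phase) {
  tab <- table[table$phase == phase, , drop = FALSE]
  tab$value[tab$flag] <- NA_real_
  units <- unique(tab[, c("subject", "roi")])
  feats <- unique(tab$feature)
  X <- matrix(NA_real_, nrow = nrow(units), ncol = length(feats),
              dimnames = list(paste(units$subject, units$roi, sep = ":"), feats))
  key_row <- match(paste(tab$subject, tab$roi, sep = ":"), rownames(X))
  key_col <- match(tab$feature, feats)
  X[cbind(key_row, key_col)] <- tab$value
  list(X = X, labels = as.integer(units$roi == "tumor"), units = units)
}

#' Phase-wise LOO classification of healthy vs tumor ROIs
#'
#' For each of the seven phases, builds the ROI-by-feature matrix from
#' that phase's feature vectors and evaluates leave-one-out classification.
#'
#' @param table long feature table over tumor and healthy ROIs
#'   (see [cohort_feature_table()]).
#' @param cfg a [classifier_config()].
#' @return data.frame with one row per phase: phase, auc, ci_low,
#'   ci_high, n; attribute \code{"probabilities"} holds the per-phase
#'   out-of-fold probability vectors.
#' @export
classify_by_phase <- function(table, cfg = classifier_config()) {
  rows <- vector("list", 7L)
  probs <- vector("list", 7L)
  for (ph in 1:7) {
    pm <- phase_matrix(table, ph)
    keep <- rowSums(is.finite(pm$X)) > 0
    if (any(!keep))
      warning("phase ", ph, ": dropping ", sum(!keep),
              " ROI(s) with no finite feature values")
    p <- loo_probabilities(pm$X[keep, , drop = FALSE], pm$labels[keep], cfg)
    ra <- roc_auc(p, pm$labels[keep], cfg)
    rows[[ph]] <- data.frame(phase = ph, auc = ra$auc, ci_low = ra$ci_low,
                             ci_high = ra$ci_high, n = sum(keep))
    probs[[ph]] <- stats::setNames(p, rownames(pm$X)[keep])
  }
  out <- do.call(rbind, rows)
  attr(out, "probabilities") <- probs
  out
}
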