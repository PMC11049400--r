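make_long <- function(values_fun, n_subj = 2, phases = 1:7,
                      feature = "f1", roi = "tumor") {
  rows <- expand.grid(subject = paste0("S", seq_len(n_subj)), phase = phases,
                      stringsAsFactors = FALSE)
  rows$roi <- roi
  rows$feature <- feature
  rows$value <- values_fun(rows$subject, rows$phase)
  rows$flag <- FALSE
  rows
}

test_that("balanced within-subject slope is recovered by the mixed model", {
  set.seed(0)
  df <- make_long(function(s, ph) 2 * ph + ifelse(s == "S1", 0, 10) +
                    rnorm(length(ph), sd = 1e-6))
  fit <- fit_lmm(df)
  expect_true(fit$converged)
  expect_equal(fit$estimate, 2, tolerance = 1e-3)
  expect_lt(fit$p, 0.05)
})

test_that("degenerate features are excluded, not fitted", {
  df <- make_long(function(s, ph) rep(5, length(ph)))
  fit <- fit_lmm(df)
  expect_true(fit$excluded)
  expect_false(fit$converged)
  expect_true(is.na(fit$p))
  # single subject is not a mixed-model design
  df1 <- make_long(function(s, ph) ph + rnorm(length(ph)), n_subj = 1)
  expect_true(fit_lmm(df1)$excluded)
})

test_that("categorical coding detects non-monotone profiles", {
  set.seed(1)
  peak <- c(0, 0, 5, 10, 5, 0, 0)
  df <- make_long(function(s, ph) peak[ph] + rnorm(length(ph), sd = 0.2),
                  n_subj = 5)
  num <- fit_lmm(df, stats_config(timepoint_coding = "numeric"))
  cat <- fit_lmm(df, stats_config(timepoint_coding = "categorical"))
  expect_lt(cat$p, 1e-6)      # joint F-test sees the peak
  expect_gt(num$p, cat$p)     # symmetric profile has ~zero linear slope
})

test_that("Benjamini-Hochberg adjustment follows the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_fdr(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(bh_fdr(0.2), 0.2)
  p <- runif(20)
  q <- bh_fdr(p)
  expect_true(all(q >= p - 1e-15))
  expect_true(all(q <= 1))
})

test_that("significance requires the joint p and FDR rule", {
  res <- data.frame(feature = c("a", "b", "c"),
                    p = c(0.01, 0.01, NA),
                    q = c(0.04, 0.08, NA),
                    converged = c(TRUE, TRUE, FALSE),
                    excluded = c(FALSE, FALSE, TRUE))
  expect_equal(significant_features(res), "a")
})

test_that("mixed-model screen is calibrated on null data", {
  set.seed(1)
  n_feat <- 300
  rows <- list()
  for (f in seq_len(n_feat)) {
    df <- make_long(function(s, ph) rnorm(length(ph)), n_subj = 7,
                    feature = sprintf("null%03d", f))
    rows[[f]] <- df
  }
  tab <- do.call(rbind, rows)
  res <- screen_features(tab, roi = "tumor")
  frac <- mean(res$p < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.09)
  # joint p/FDR rule admits almost nothing under the null
  expect_lte(mean(res$significant), 0.05)
})

test_that("z-scored profiles have mean zero and unit sample sd", {
  tab <- make_long(function(s, ph) ph * 1.0, n_subj = 3)
  z <- zscore_profile(tab, "f1")
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(unname(z[1]), min(z))

  # 3-phase toy: means 1,2,3 -> z = (-1, 0, 1)
  tab3 <- make_long(function(s, ph) ph * 1.0, n_subj = 2, phases = 1:3)
  expect_equal(unname(zscore_profile(tab3, "f1")), c(-1, 0, 1),
               ignore_attr = TRUE)

  # constant profile: zeros plus flag
  tabc <- make_long(function(s, ph) rep(3, length(ph)))
  zc <- zscore_profile(tabc, "f1")
  expect_equal(unname(zc), rep(0, 7), ignore_attr = TRUE)
  expect_true(attr(zc, "constant"))
})

test_that("complete-linkage clustering separates opposite temporal templates", {
  set.seed(0)
  up <- seq(-1, 1, length.out = 7)
  profs <- rbind(
    t(replicate(10, up + rnorm(7, sd = 0.05))),
    t(replicate(10, rev(up) + rnorm(7, sd = 0.05))))
  rownames(profs) <- paste0("f", 1:20)
  cl <- cluster_profiles(profs, k = 2)
  expect_equal(length(unique(cl$cluster[1:10])), 1)
  expect_equal(length(unique(cl$cluster[11:20])), 1)
  expect_false(cl$cluster[1] == cl$cluster[20])

  # automatic k via the merge-height gap finds the two templates
  cl_auto <- cluster_profiles(profs)
  expect_equal(cl_auto$k, 2L)

  # identical profiles merge at height zero
  two <- rbind(a = up, b = up)
  cl2 <- cluster_profiles(two, k = 1)
  expect_equal(unname(cl2$cluster), c(1L, 1L))
  expect_equal(cluster_profiles(two, k = 2)$tree$height[1], 0)

  # k = 1 puts everything together
  expect_equal(unique(unname(cluster_profiles(profs, k = 1)$cluster)), 1L)
})
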