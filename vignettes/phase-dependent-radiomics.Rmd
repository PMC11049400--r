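---
title: "Phase-dependent radiomics in dynamic contrast-enhanced imaging: models and methods"
author: "dceradiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-dependent radiomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Radiomics features extracted from contrast-enhanced CT or MRI depend on
*when* in the bolus passage the image was acquired. Inter-patient
differences in cardiac output and blood volume shift the arrival and
shape of the contrast bolus, so a fixed scan delay samples different
contrast phases in different patients, and any feature that responds to
enhancement becomes patient-dependent noise. This package implements a
pipeline to quantify that effect: synchronize dynamic series to a common
set of seven contrast phases defined from a reference vessel, extract a
standard radiomics battery per phase, screen features for temporal
dependence with linear mixed models, and measure how healthy-vs-tumor
classification accuracy depends on phase. Because clinical dynamic
series are rarely shareable, the package ships a synthetic phantom
cohort generator with known ground truth on which every stage is
exercised and tested.

## The phantom cohort model

The phantom emulates a dynamic contrast-enhanced CT acquisition of a
tumor-bearing region with a reference vessel.

**Acquisition grid.** Scans are placed at 1.5 s intervals for the first
20 scans and 3 s intervals afterwards (26 scans by default, so the
series spans 0-46.5 s). An MR mode uses a uniform 4.22 s grid instead;
its mechanics are otherwise identical.

**Arterial input function.** The vessel follows a first-pass
gamma-variate bolus on top of a 60 HU blood baseline:

$$\mathrm{AIF}(t) = A \left(\frac{t - t_0}{\alpha\beta}\right)^{\alpha}
  \exp\!\left(\alpha - \frac{t - t_0}{\beta}\right), \qquad t > t_0,$$

which peaks at exactly $A$ when $t = t_0 + \alpha\beta$. Per patient,
the peak time is drawn uniformly from 15-26 s and the peak intensity
from 520-827 HU, with arrival $t_0 \sim U(4, 8)$ s and shape
$\alpha = 3$; $\beta$ follows from the drawn peak time. These ranges are
the study conditions the phantom is calibrated to; recirculation is
deliberately omitted (first-pass only).

**Tissue kinetics.** Tumor and healthy ROIs follow a one-compartment
uptake model,

$$C(t) = \mathrm{baseline} + k_\mathrm{in} \int_0^t \mathrm{AIF}(s)\,
  e^{-k_\mathrm{out}(t-s)}\, ds,$$

evaluated by trapezoidal quadrature on a 0.25 s internal grid (the
quadrature step is small against both the scan spacing and
$1/k_\mathrm{out}$; the unit tests compare it with the closed form for a
constant input). Defaults give the tumor rapid, intense uptake
($k_\mathrm{in} = 0.010\,\mathrm{s}^{-1}$, peak enhancement on the order
of +100 HU) and healthy tissue a weaker response
($k_\mathrm{in} = 0.004\,\mathrm{s}^{-1}$, about +40 HU), both with
$k_\mathrm{out} = 0.025\,\mathrm{s}^{-1}$ and a shared 35 HU baseline.
Before bolus arrival the two tissues are statistically
indistinguishable — the class contrast is entirely phase-gated, which is
what lets the classification experiment measure phase dependence.

**Texture.** Each tissue ROI carries a static spatially correlated
random field (white noise smoothed with a 3 mm Gaussian, normalized to
unit variance). A voxel at time $t$ takes

$$x_v(t) = C(t) + \tau_v \left(a_0 + f\,(C(t) - \mathrm{baseline})\right)
  + \varepsilon,$$

with static amplitude $a_0 = 8$ HU, enhancement-coupling fraction
$f = 0.10$ and i.i.d. Gaussian noise $\varepsilon$ (sd 10 HU). The
coupling term makes the spatial contrast of the ROI grow with
enhancement, so second-order texture features genuinely change with
phase — the premise under study — with known ground truth. The phantom
does not attempt realistic anatomy, photon-counting noise, motion, or
partial-volume effects; conclusions from phantom tests are about the
pipeline's correctness and sensitivity, not about tissue biology.

## Phase synchronization

The vessel ROI is reduced to its median intensity per scan. Seven
phases are then fixed:

* **TP1** — the second acquired scan (pre-bolus reference).
* **TP2** — the scan closest to an increase of at least 15 % over the
  mean of the first two scans. We read "closest to an increase of at
  least 15 %" as an *event*: the earliest scan at or above the 115 %
  level. The mirrored washout rule (TP6, "last scan with intensity at
  least 15 % higher than the mean of the last two scans") is
  unambiguously a last-crossing, and symmetry favors the same
  semantics on the rising side. A nearest-to-level variant is available
  as a config option.
* **TP4** — the scan with peak median intensity; ties break to the
  earliest scan (first-pass peak).
* **TP3 / TP5** — the scans closest to the midpoint between TP2-TP4 and
  TP4-TP6 respectively, measured on the *acquisition-time* axis, because
  the scan interval changes from 1.5 s to 3 s mid-series and an index
  midpoint would be biased late. Ties break to the earlier scan. An
  index-axis option exists.
* **TP7** — the second-to-last scan.

Degenerate curves raise errors rather than returning nonsense: a curve
that never crosses the rise threshold has "no bolus", a strictly rising
curve has "no washout", and a non-monotone assignment reports "phase
ordering violated". The assignment is invariant under positive scaling
of the curve (the thresholds are relative) but *not* under additive
offsets, which change relative rises; this is intentional and tested.

## The feature battery

Per ROI and phase the package computes 86 features on each image set:
18 first-order, 22 GLCM, 14 GLDM, 16 GLRLM and 16 GLSZM. Image sets are
the original volume, Laplacian-of-Gaussian responses at sigma 1-5 mm
(CT preset; 2-5 mm for MR), and 8 wavelet sub-bands — 14 sets for CT
(1204 features), 13 for MR (1118). Shape features are excluded by
construction: masks are propagated unchanged across a series, so shape
cannot carry temporal information.

**Preprocessing.** CT: resample to 1 mm isotropic (separable Keys cubic
interpolation for the image, nearest neighbor for the mask) and crop to
the mask bounding box plus a 10-voxel pad. MR: additionally z-score the
whole volume and scale by 100 before resampling to 2 mm. Gray levels are
discretized with a fixed bin width (25 HU for CT, 5 for MR) anchored at
the ROI minimum: $\ell(x) = \lfloor (x - \min x)/w \rfloor + 1$. The
energy family (Energy, TotalEnergy, RMS) adds a voxel-array shift
(1000 for CT, 300 for MR) so negative CT numbers are not squared into
ambiguity.

**Texture conventions.** All matrices are built over the gray levels
actually present in the ROI (empty levels dropped). GLCM and GLRLM use
the 13 unique 3D direction offsets at distance 1, normalized per
direction, with feature values averaged over directions that contain at
least one pair. GLSZM zones and GLDM dependencies use 26-connectivity;
the dependence count includes the center voxel and uses threshold
$\alpha = 0$ (equal levels only). Of the commonly implemented GLCM
features we compute the 22 obtained by omitting SumAverage (a duplicate
of JointAverage under matrix symmetry) and the maximal correlation
coefficient. Degenerate inputs return defined fallbacks instead of
crashing — a single-gray-level ROI has Correlation 1, a single-voxel ROI
has no co-occurrence pairs and yields NA — and every fallback is
reported through a flag column that the statistics stage treats as
missing data.

Correctness is established against an independent brute-force oracle: a
second implementation of every matrix and formula written as direct
scalar-loop enumeration, kept in the test helpers and compared on
randomized small ROIs to within $10^{-6}$ relative.

**Filters.** The LoG filter is separable
second-derivative-of-Gaussian filtering with sigma specified in
millimetres and converted to voxel units through the spacing, replicate
boundary handling, and $\sigma^2$ scale normalization. For the wavelet
sets the package uses a single-level *undecimated* (stationary) 3D
transform with the Coiflet-1 filter pair, centered windows and mirror
boundaries. Shift-equivariance is essential here: with a decimated
transform, sub-band statistics inside an ROI depend on how the ROI
happens to align with the decimation grid, which injects a purely
geometric signal into the features (we observed this directly on the
phantom, where it manufactured tumor/healthy separability before
contrast arrival). The decimated orthonormal variant is retained as
`dwt3()` where its exact energy partition (Parseval) is the property of
interest.

## Temporal statistics

For each feature and ROI the screen fits the linear mixed model
`value ~ phase + (1 | patient)` by REML (an additional `(1 | visit)`
intercept is available for repeated-visit designs), with the p-value
for the phase effect from the Satterthwaite degrees-of-freedom
approximation. Phase enters as a numeric 1-7 covariate by default — a
single slope coefficient — with a categorical option whose joint F-test
catches non-monotone profiles (the unit tests include a symmetric
peaked profile that the numeric coding misses by construction).
Zero-variance features and failed fits are *excluded* from the FDR
universe rather than assigned p-values. Benjamini-Hochberg adjustment is
applied to the converged p-values and a feature is called significant
only under the joint rule p < 0.05 AND q < 0.05.

Significant features are summarized by their mean profile over patients
at each phase, z-scored across the seven phase means (sample sd;
constant profiles return zeros and a flag), and clustered with complete
linkage on Euclidean distances. When no cluster count is given, the cut
is placed at the largest relative gap between successive merge heights,
searched over 2-9 clusters — a transparent rule that recovers cleanly
separated temporal templates and is deliberately simple; for anything
subtle, pass `k` explicitly.

The screen's calibration is verified on independent null features
(raw p < 0.05 fraction within Monte-Carlo bounds of 5 %, and the joint
rule admitting essentially nothing), and its power on the phantom's
enhancement-coupled features; a no-uptake phantom cohort run through
the identical pipeline stays null.

## Phase-wise classification

Healthy and tumor ROIs are classified per phase with L2-penalized
logistic regression at regularization strength C = 1, i.e.

$$\min_{w, b}\ \tfrac12 \lVert w \rVert^2 +
  C \sum_i \log\!\left(1 + e^{-\tilde y_i (x_i^\top w + b)}\right),$$

with an unpenalized intercept, evaluated by leave-one-out
cross-validation (each ROI predicted by a model trained without it;
missing values imputed with training-fold medians). The solver exploits
that the optimal $w$ lies in the row span of the feature matrix and
runs damped Newton iterations in the $(n+1)$-dimensional dual — exact,
deterministic, and indifferent to raw feature scales up to $10^{10}$
where generic coordinate-descent fitters abort; agreement with an
independent ridge implementation on standardized problems is part of
the test suite. AUC is the Mann-Whitney pair statistic with ties
counted one half; confidence intervals are DeLong by default with a
bootstrap option.

Two practical points, both visible in the package's own experiments:

* **Raw scales disable the penalty.** Radiomics features span ~10
  orders of magnitude, so at C = 1 the ridge term is vacuous against
  unstandardized features and the fit is effectively unregularized. The
  classifier therefore defaults to no scaling (matching a plain
  logistic-regression setup) but the pipeline's phantom experiment
  enables within-fold z-scaling, computed on each training fold only.
* **LOO is pessimistic near chance.** With 14 ROIs and ~1200 features,
  leaving a sample out shifts its own class statistics away from it, so
  the null distribution of LOO AUC is biased *below* 0.5 (label
  permutation on a pre-bolus phantom matrix gives mean ≈ 0.4, sd ≈ 0.2).
  Pre-bolus AUCs scattered at or below 0.5 therefore mean "no signal",
  and the meaningful acceptance check is the absence of above-chance
  pre-bolus signal together with near-perfect discrimination at peak
  enhancement.

## Numerical and design choices

* Geometry checks use 1e-6 relative tolerance on spacing; volumes are
  index-ordered (i, j, k) with spacing in mm, one convention asserted at
  every boundary.
* NRRD I/O covers attached headers, raw little-endian and ascii
  encodings; integer data round-trips bit-exactly.
* Mask propagation across a series is an identity copy guarded by a
  geometry-equality precondition (same-session, same-grid series; no
  registration).
* The tissue-curve quadrature step (0.25 s), the Newton convergence
  criterion (relative objective change ≤ 1e-12, 200-iteration cap) and
  the wavelet/LoG boundary modes are pinned in code and config for
  determinism; pipeline reruns are byte-identical.
* All randomness flows from one master seed: per-patient seeds are
  derived deterministically from it, and generators restore the
  caller's RNG state.
* Test and acceptance problem sizes — 32^3 grids, 26 scans, 7 patients,
  4^3 oracle ROIs, 1000 null features — are the package's chosen
  trade-off between statistical resolution and a test suite that runs
  in minutes.

## Limitations

The phantom's simplicity is deliberate but real: Gaussian noise only,
no anatomy or motion, first-pass bolus without recirculation, and
texture modelled as a multiplicative stationary field. A pipeline that
passes every phantom test can still be confounded on clinical data by
segmentation error, motion between scans, or scanner-specific intensity
calibration — none of which the phantom represents. The automatic
cluster-count rule is a heuristic; the MR preset applies the same phase
algorithm that the CT path uses, where clinical practice may identify
phases manually; and the classifier experiments are bound to small-n
LOO behavior discussed above.
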