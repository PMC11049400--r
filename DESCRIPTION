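Package: dceradiomics
Title: Contrast-Phase-Dependent Radiomics for Dynamic Contrast-Enhanced CT and MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how contrast-agent dynamics shape radiomics
    profiles in dynamic contrast-enhanced (DCE) CT and MRI. Provides a
    synthetic DCE phantom cohort generator with known ground truth
    (gamma-variate arterial input function, compartmental tissue uptake,
    enhancement-coupled texture), reference-vessel-based synchronization of
    image series to seven contrast-agent phases, an intensity and texture
    radiomics feature battery (first-order, GLCM, GLDM, GLRLM, GLSZM over
    original, Laplacian-of-Gaussian and 3D wavelet image sets), a linear
    mixed-model screen for phase-dependent features with false-discovery-rate
    control and profile clustering, and phase-wise healthy-versus-tumor
    classification with L2-penalized logistic regression under leave-one-out
    cross-validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lmerTest,
    pROC,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
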