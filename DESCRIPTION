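Package: radgs
Title: Radiomics Prediction of Prostate Cancer Gleason Grade from
    Multiparametric MRI with Region-of-Interest Inflation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting prostate-cancer Gleason grade group from
    co-registered quantitative multiparametric MRI maps (apparent diffusion
    coefficient, T2 relaxation time, and dynamic contrast-enhanced signal
    enhancement rate). Implements per-pixel parameter-map fitting from raw
    signal series, gray-level co-occurrence matrix texture features averaged
    over four directions, iterated binary dilation of radiologist-drawn
    lesion masks ("ROI inflation"), ReliefF feature selection with a
    positive-weight retention rule, SMOTE class balancing applied strictly
    inside training folds, and stratified cross-validated classification
    with RBF support vector machines, k-nearest neighbours, and a Gaussian
    naive Bayes classifier. A synthetic-data module generates image phantoms
    and class-conditional feature tables with the statistical structure of a
    small surgical mp-MRI cohort, so the full pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    e1071,
    minpack.lm,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
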