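Package: rpvpipe
Title: Multi-Region CT Radiomics Signatures with Reproducibility
    Filtering, Harmonisation and Survival Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end pipeline for building and evaluating composite
    radiomics predictive vectors (RPVs) from multi-region chest CT
    segmentations.  Provides a synthetic phantom cohort generator; ROI
    geometry (resampling to a common voxel grid, perilesional annulus
    derivation, parenchymal patch placement); a 666-feature-per-ROI
    catalogue of first-order, grey-level co-occurrence texture, shape and
    box-counting fractal-dimension features over original, wavelet-,
    Laplacian-of-Gaussian- and wavelet-LoG-filtered images; two-way random
    intraclass-correlation reproducibility filtering; feature
    standardisation with empirical-Bayes ComBat batch harmonisation;
    Spearman redundancy reduction with LASSO logistic signature fitting and
    a selector-by-learner benchmark; and evaluation by ROC analysis with
    bootstrap confidence intervals, uni-/multivariable logistic models with
    a nomogram, Kaplan-Meier/log-rank/Cox prognostic stratification, and
    cohort-comparison statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    survival,
    RNifti,
    jsonlite,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    pROC,
    sva,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
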