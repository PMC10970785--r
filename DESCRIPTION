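Package: tissueprint
Title: Multivariate Modeling and Validation of Ambient Mass-Spectrometry Tissue Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds, validates, and refines PCA-LDA molecular models that
    classify biological tissue from handheld ambient mass-spectrometry
    fingerprints. Provides spectral binning, quality-control filtering and
    normalization of per-scan peak lists; supervised PCA-LDA fitting under
    component-count rules that guard against overfitting; Mahalanobis-distance
    class probabilities with no-call thresholding and outlier detection;
    specimen-aware cross-validation with permutation and pseudo-class
    controls, learning curves, and confusion-matrix, kappa and AUROC metrics;
    loading-based sparse feature selection with annotation-driven exclusion
    of artifactual ions; and a seeded synthetic-spectrum generator so the
    whole workflow can be exercised without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    withr,
    optparse,
    mzR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
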