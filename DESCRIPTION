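Package: smbplsr
Title: Sparse Multi-Block Partial Least Squares Regression for Multi-Omics Data Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Fits sparse multi-block partial least squares regression (sMBPLSR)
    models for classification and regression on several horizontally linked
    omics blocks (untargeted LC-MS metabolomics, short-chain fatty acid panels,
    taxa relative abundances). Provides NIPALS estimation with soft-thresholded
    loading weights for variable selection, consensus PCA for unsupervised
    overview, Pareto scaling and Frobenius block normalization, QC-based
    signal-drift correction and blank/mass filtering for feature tables,
    leave-one-subject-out cross-validation with per-component degree-of-sparsity
    optimization and one-standard-error component selection, biomarker reporting
    with one-way ANOVA on log intensities, correlation-loading analytics, and a
    synthetic multi-block study generator with planted ground truth for recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
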