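Package: factorlens
Title: Symbolic Regression and Mutual-Information Brain Networks for
    Non-Linear Tensor Factorizations of fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Interprets deep non-linear tensor factorizations of 4D fMRI
    volumes. An equation-learner network whose hidden units apply elementary
    mathematical operators (sin, cos, product, safeguarded quotient, ...)
    is trained on coordinate-encoded factor matrices under a smoothed-L1/2
    sparsity penalty and distilled into closed-form formulas by coefficient
    thresholding. Mode-product tensor algebra rebuilds volume frames from
    factor matrices and a constant core tensor and merges them into a 4D
    reference tensor. A histogram mutual-information pipeline extracts
    regional time series from a labeled parcellation, builds symmetric
    connectivity matrices, partitions them into subnetworks, and compares
    groups edgewise with ANCOVA and Benjamini-Hochberg false-discovery-rate
    control. Seeded synthetic generators (factor surfaces, factorized
    tensors, phantom parcellations, two-group time series with planted
    connectivity differences) make the full workflow runnable without any
    imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
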