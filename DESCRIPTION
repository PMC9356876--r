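Package: fundusreg
Title: Vascular-Landmark Detection and Feature-Based Retinal Image Registration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Two-stage vascular landmark detection and feature-based
    registration of retinal fundus image pairs. Provides an encoder-decoder
    vessel segmentation network with multi-input and connected-convolution
    modules, an anchor-based junction (bifurcation/crossover) detection
    network with a feature pyramid and focal/smooth-L1 losses, skeleton
    crossing-number calibration of detected junctions, SIFT-style orientation
    descriptors with ratio-test matching, RANSAC projective homography
    estimation, and an evaluation suite (confusion metrics, ROC AUC, and the
    error-threshold success-rate curve). A synthetic fundus generator produces
    branching vascular phantoms and registered image pairs with exhaustive
    ground truth, so the full pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    png,
    jpeg,
    tiff,
    jsonlite,
    yaml,
    pROC,
    withr,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
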