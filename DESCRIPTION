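Package: tsliceattn
Title: T-Distribution Slice Attention and Penalty-Weight Loss for MRI Stack Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies stacks of 2-D grayscale image slices (knee-MRI-style
    exams) with a convolutional backbone, a Student-t slice-attention module
    that up-weights informative central slices, and a cost-sensitive
    penalty-weight loss that replaces cross-entropy. Includes the full
    evaluation protocol (ROC/AUC, adaptive accuracy-maximizing threshold,
    best-validation-AUC epoch selection), a synthetic phantom generator that
    emulates MRNet-like exams (variable slice counts, central lesions, noisy
    end slices, class imbalance), stratified splitting, and a reproducible
    train/evaluate/ablate pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
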