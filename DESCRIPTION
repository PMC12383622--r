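Package: akbseg
Title: Adaptive-Kernel and Bidirectional-Pyramid Instance Segmentation for Cell Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Single-stage instance segmentation of cells in bright-field
    microscopy images, built around three architectural ideas: adaptive-kernel
    convolution (AKConv) with a learned per-position offset field and an
    arbitrary number of sampling points, a bidirectional feature pyramid
    (BiFPN) with fast-normalized weighted fusion, and Gaussian Soft-NMS score
    decay for densely adherent cells. Includes a CLAHE + Gaussian-blur
    preprocessing pipeline, the training objective (cross-entropy,
    squared-error box regression, binary cross-entropy masks), evaluation
    (precision, recall, AP/mAP50 for boxes and masks, paired t-tests,
    parameter accounting), confluence and cell-count analytics, and a seeded
    synthetic scene generator so the whole pipeline is testable without
    microscope data. All network layers, including backpropagation, are
    implemented in R and C++; no external deep-learning runtime is required.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    mgcv,
    png,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
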