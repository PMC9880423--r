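Package: tillerest
Title: Tiller Number Estimation from Side-View Plant Images with
    Self-Supervised Convolutional Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the number of tillers (basal shoots) of a grass
    plant from a single side-view RGB image.  Implements the full
    pipeline: procedural generation of synthetic potted-plant scenes
    with known tiller counts, pot-anchored geometric normalization to a
    224x224 canvas, colour-space plant segmentation (HSV saturation and
    Lab a/b thresholds combined by logical union), self-supervised
    pretext-task pretraining of a convolutional backbone on plant area
    or aspect-ratio labels (continuous or equal-frequency discretized),
    feature extraction from the headless backbone, tiller-count
    regression by support vector regression or a frozen-backbone linear
    head, the conventional linear baseline built on plant area and
    aspect ratio, and a six-fold cross-validated evaluation harness
    reporting mean absolute error with standard error and confidence
    intervals.  Includes a small single-precision CNN training engine
    (convolution, pooling, dense layers, Adam) written with
    RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    png,
    yaml,
    jsonlite,
    withr,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
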