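Package: mlgleason
Title: Multi-Label Ensemble CNN Classification for Patch-Level Gleason Grading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for patch-level Gleason grading of prostate histopathology
    that replace noisy majority-vote patch labels with threshold-based
    multi-labels. Provides an audit of the label noise that majority voting
    induces on pixel-annotated patch datasets, a truncated ResNet18-style
    binary convolutional network trained one-vs-all per Gleason grade
    (Adam, weighted cross-entropy, stepped learning-rate schedule with a
    faster head, early stopping, on-the-fly augmentation), an ensemble
    decision rule producing multi-label patch hypotheses with per-class
    thresholds selected from validation precision-recall curves, full
    precision/recall/F1 evaluation, Grad-CAM patch heatmaps and stitched
    whole-slide activation maps, and a deterministic synthetic slide/patch
    generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
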