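Package: glandseg
Title: Mammary Gland Segmentation and Breast Composition from MLO Mammograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automatic mammary-gland region extraction and breast
    composition evaluation on mediolateral-oblique (MLO) mammograms.
    Implements objective gland extraction by peak-count-switched histogram
    thresholding (Kapur maximum-entropy for unimodal histograms, Otsu
    discriminant analysis for multimodal ones), emulation of the
    semi-subjective physician correction that deletes non-gland structures,
    mammary gland content ratio and four-category breast composition
    classification, image preprocessing (bit-depth reduction, padding,
    nearest-neighbour resizing, orientation datasets), a configurable U-Net
    segmentation model with a native C++ training engine, and Dice-based
    evaluation stratified by breast composition, including the complement
    rule for gland-free images. A synthetic MLO phantom generator with exact
    ground truth makes the whole pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    png,
    tiff,
    EBImage,
    jsonlite,
    yaml,
    readr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
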