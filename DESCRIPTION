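Package: mammoseg
Title: Two-Stage Hybrid U-Net Training and Size-Stratified Evaluation for
    Mammographic Lesion Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying abnormal-focused lesion segmentation in
    screening mammography at desk scale. Provides a synthetic phantom
    generator that emits grayscale breast images with exact binary lesion
    masks of controlled pixel area; CLAHE-based preprocessing, mask
    binarization, resizing and lesion-preserving augmentation; lesion-centered
    patch extraction with ratio-controlled negative sampling; a compact
    encoder-decoder convolutional segmentation network (U-Net) implemented
    with 'RcppArmadillo' including full backpropagation and Adam optimisation;
    a composite focal plus Tversky training loss; a two-stage training
    protocol (patch pretraining, encoder transfer, full-image fine-tuning
    with hybrid patch substitution); and a size-stratified evaluation
    framework (Dice, IoU, pixel accuracy, symmetric Hausdorff distance,
    IoU-thresholded detection rates, Kruskal-Wallis and rank-sum group
    comparisons, and resolution-budget analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    tiff
Config/testthat/edition: 3
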