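Package: rdaunet
Title: Residual-Dense Attention U-Net for CT Bladder and Lesion Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Slice-wise semantic segmentation of the bladder and bladder
    lesions on abdominal computed tomography. Implements the full pipeline:
    Hounsfield-unit windowing and image/mask preprocessing, joint five-way
    affine augmentation of image/mask pairs, a five-level encoder-decoder
    network combining residual stages, dense stages and additive attention
    gates on the skip connections, a seeded ADAM training loop, and a
    four-metric evaluation suite (pixel accuracy, Dice, intersection over
    union, average Hausdorff distance) plus rank-based ROC-AUC. A synthetic
    CT phantom generator with exact ground truth makes every stage testable
    without clinical data. The convolutional network engine (layers,
    reverse-mode gradients, optimizer) is implemented in C++ via
    'RcppArmadillo'.
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
    purrr,
    ggplot2,
    generics,
    png,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    jsonlite
Config/testthat/edition: 3
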