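Package: dermapatch
Title: Patch-Based Residual Networks and Multimodal Fusion for Skin Lesion Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid framework for binary skin-disease detection from RGB
    images and clinical metadata. Images are preprocessed (resampling,
    adaptive non-local-means denoising, Otsu skin masking, min-max
    normalisation, augmentation), tiled into patches, and classified by a
    fully convolutional residual network (FCRN) whose per-patch diseased
    probabilities are max-aggregated into an interpretable per-pixel disease
    probability map. High-risk map regions are reduced to a compact tensor
    and fused with z-scored and one-hot encoded clinical covariates in a
    second convolutional network for the final image-level classification.
    Includes a synthetic-cohort generator with controllable image and
    clinical effect sizes, an evaluation harness (stratified splits, k-fold
    cross-validation, grid search, confusion-matrix metrics and rank-based
    AUC), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
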