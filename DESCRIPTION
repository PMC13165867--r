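Package: imauseg
Title: Hybrid Inception Multi-Scale U-Net for Laparoscopic Liver
    Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Implements IMAU-Net, a hybrid encoder-decoder for binary
    segmentation of the liver in laparoscopic frames: an InceptionV3
    feature extractor feeding a bottleneck that fuses a Multi-Core
    Pooling block (parallel stride-one max pools at kernel sizes 2, 3
    and 5) with an improved atrous spatial pyramid pooling block
    (dilations 2, 4, 6, 8 plus image-level pooling), decoded through
    transposed convolutions with resize-based skip fusion. Ships a
    pure-array neural-network engine (convolution, transposed
    convolution, pooling, batch normalization, bilinear resize, with
    analytic gradients and Adam), a synthetic laparoscopic scene
    generator, a CLAHE/denoise/morphology preprocessing pipeline,
    overlap and boundary metrics (Dice, IoU, precision/recall, MAE,
    HD95, ROC AUC) with a soft Dice training loss, stratified
    cross-validation and ablation harnesses, fold aggregation and
    paired statistics, occlusion-based explainability, and PNG dataset
    input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
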