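Package: LumenSeg
Title: Spatial-Temporal Ensembles for Lumen Segmentation in Endoscopic Video
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Segmentation of the hollow lumen in ureteroscopy video by an
    ensemble of convolutional segmentation models. Two single-frame cores --
    a residual-block U-Net trained with the Dice loss and a proposal-based
    instance segmenter behind an instance-to-lumen adapter -- are each
    extended to multi-frame models by prepending a 3D convolution over
    triplets of consecutive frames, and the member probability maps are fused
    by arithmetic averaging. Includes overlap metrics (Dice, precision,
    recall), Kruskal-Wallis model comparison, paired image/mask augmentation,
    patient-wise cross-validation with grid search, and a seeded synthetic
    ureteroscopy-video generator with exact ground-truth masks for
    self-contained experimentation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
biocViews: ImageSegmentation, Visualization, Classification
RoxygenNote: 7.3.3
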