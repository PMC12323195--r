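Package: NSRscreen
Title: Device-Independent Niacin Skin-Flushing Response Screening
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification of the niacin skin-flushing response (NSR) from
    forearm photographs and machine-learning screening of psychiatric
    disorders. Provides white-reference colour correction and fiducial-based
    scale calibration of arm images, an encoder-decoder (U-Net) semantic
    segmentation model for flushing-area detection with patient-level data
    splits and Dice/IoU evaluation, normalized-area (A_norm) quantification
    with an objective 3-scale score, 20-dimensional concentration-by-time
    feature vectors, and a SMOTE-balanced, grid-searched kernel-SVM screening
    harness with stratified cross-validation. A synthetic cohort and image
    generator emulates the open NSR dataset layout so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    png,
    EBImage,
    e1071,
    S4Vectors,
    SummarizedExperiment,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
biocViews: ImageSegmentation, Classification, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'NSRscreen-package.R'
    'RcppExports.R'
    'classify.R'
    'io.R'
    'preprocess.R'
    'quantify.R'
    'reference.R'
    'segmentation.R'
    'synthetic.R'
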