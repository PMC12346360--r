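Package: thioseg
Title: Weakly Supervised Segmentation and Morphometry of Thioflavin-S
    Amyloid Deposits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for segmenting and profiling thioflavin-S-positive
    parenchymal amyloid deposits in fluorescence micrographs using only
    image-level (patch) labels. The pipeline covers retrospective
    multi-image illumination correction and gradient-based background
    estimation, a compact fully convolutional classifier with a
    thresholded-average-pooling head for class-activation-map (CAM)
    localization, conversion of CAMs into object and background banks by
    two-level thresholding with inpainting, copy-paste object-level
    augmentation with contour perturbation and soft blending, a
    valid-convolution encoder-decoder segmenter trained with the
    asymmetric unified focal loss, overlap-tile inference, per-deposit
    morphometry (including box-counting fractal dimension and
    lacunarity), and patient-wise cross-validated evaluation with PCA
    and ANOVA group comparison. A seeded synthetic-micrograph generator
    provides cohorts with known ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
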