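Package: femaug
Title: Attribute-Augmented U-Net Segmentation of the Left Femur in CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end pipeline for automatic left-femur segmentation in
    lower-abdomen computed tomography: Hounsfield-unit window leveling to
    8-bit grayscale, histogram-projection bounding-box localization of the
    femur pair, fixed-size cropping, lying-posture attribute augmentation
    (a constant feature column appended to each slice), a five-level U-Net
    trained with binary cross-entropy and Adam, and evaluation by Dice
    similarity coefficient, intersection over union, spectral angle mapper,
    and the structural similarity index on orthographic renders of the
    reconstructed 3D mask. Includes a geometric CT phantom generator with
    paired femur structures and ground-truth masks so that every stage is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    png,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
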