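Package: limbicnet
Title: Restoration, Limbic Cropping and 3D Residual CNN Classification of FDG-PET-Like Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study how image restoration and anatomical cropping
    affect deep-learning classification of FDG-PET brain volumes. Generates
    synthetic two-class brain-phantom cohorts with regional hypometabolism,
    scanner-dependent blur and noise; restores volumes slice-wise by fast
    total-variation l1 deblurring (half-quadratic splitting) or the median
    modified Wiener filter; crops volumes to the axial slab covering the
    limbic system; trains a small 3D residual convolutional network with
    batch normalization, Adam and cross-entropy; evaluates conditions by
    stratified cross-validation (sensitivity, specificity, accuracy, F1,
    Matthews correlation coefficient); and derives class activation maps
    with per-region importance summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
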