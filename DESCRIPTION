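Package: fetalHC
Title: Fetal Head-Circumference Delineation in Ultrasound by Distance-Field Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end delineation of the fetal head circumference (HC) in
    2-D ultrasound images. A region-proposal detector with a feature-pyramid
    backbone regresses a Gaussian distance field around the skull contour
    inside detected regions; the thresholded field is fitted with a
    non-iterative least-squares ellipse and the HC length is reported in
    millimetres using the per-image pixel calibration. The package includes
    the ground-truth construction from elliptical annotations (rasterization,
    skeletonization, Gaussian-of-distance fields, bounding boxes), the staged
    training procedure with a multi-task loss, the evaluation metrics
    (signed/absolute HC difference, Hausdorff distance, Dice coefficient),
    readers and writers for the HC18-style dataset layout and COCO-style
    annotations, and a synthetic speckle-phantom generator that emulates the
    structure of fetal-ultrasound data so the whole pipeline is testable
    without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    png,
    jsonlite,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
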