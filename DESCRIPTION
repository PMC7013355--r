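Package: plcpd
Title: Probabilistic-Learning Coherent Point Drift for 3D Ultrasound Head Registration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Rigid and similarity registration of 3D ultrasound fetal-head
    acquisitions with a weighted-prior Gaussian-mixture point-set method
    (probabilistic-learning coherent point drift, PL-CPD). The pipeline covers
    confidence-map preprocessing of ultrasound volumes, texture/edge feature
    extraction, random-forest cranium segmentation with voxelwise posterior
    probabilities, construction of posterior-weighted shell point clouds, the
    EM registration core in which Gaussian-mixture membership priors are the
    classifier posteriors (uniform priors recover standard coherent point
    drift), evaluation metrics (target registration error, translation and
    rotation RMS, Dice, Hausdorff surface distance, ROC AUC), and a synthetic
    ultrasound phantom generator with known ground-truth transforms for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    pROC,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ranger,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
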