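Package: curripatch
Title: Annotation-Efficient Curriculum Learning for Patch-Based Mammography
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A patch-based curriculum-learning pipeline for breast-cancer
    detection in screening mammograms under mixed strong (lesion bounding-box)
    and weak (image-level) supervision. Provides a seeded phantom-cohort
    generator with ground-truth lesion boxes; breast-region cropping by
    patch-based tissue scanning with box co-transformation; patch tiling and
    overlap-based labeling (positive/negative/ignored/skipped); a small
    scale-invariant convolutional classifier trained in staged curricula from
    small patches to full images; breast-level evaluation (recall, precision,
    F1 aggregated over ipsilateral views and repeated runs); and Grad-CAM
    saliency maps scored against ground-truth boxes by the ground-truth
    overlap ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    EBImage,
    png,
    tiff
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
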