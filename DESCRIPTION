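Package: orbitseg
Title: Coarse-to-Fine Segmentation of the Bony Orbit in Volumetric CT and MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic three-stage segmentation of the bony orbit in
    coronal slices of volumetric CT and MRI scans: a global encoder-decoder
    network localizes the orbit region, a local network predicts a boundary
    probability map on a 128x128 region of interest, and a closed contour is
    extracted by Dijkstra shortest-path search in polar coordinates with edge
    weights inversely related to boundary probability. Includes the compact
    U-Net implementation and training loops used by both stages, slice-wise
    post-processing (adjacent-slice voting, end-slice omission), k-fold
    ensemble majority voting, segmentation evaluation metrics (two-class Dice
    per slice and per volume, centroid error, boundary mean absolute error,
    Hausdorff distance), and a seeded synthetic phantom generator that
    emulates CT-like and MRI-like orbit volumes with exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
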