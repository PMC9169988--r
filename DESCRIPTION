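Package: pentrack
Title: Semi-Supervised Motion-Based Tracking of Group-Housed Animals
    from Top-View Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A semi-supervised pipeline for long-term tracking of
    group-housed animals (e.g., pigs) in low-frame-rate top-view video.
    Detects pixels of interest from temporal intensity variation over
    flanking frame windows, refines them with Gaussian blurring and edge
    kernels, clusters contour pixels into animal identities to propose
    starting positions, tracks each animal with lightweight bounding-box
    trackers (fixed-template normalized cross-correlation or sparse
    optical flow) that can be re-seeded by human supervision events, and
    derives activity analytics: inter-animal distances, per-frame and
    accumulated movement, movement synchrony, and spatial heat maps.
    Includes a synthetic pen-scene generator with ground-truth
    trajectories and a standardized-error evaluation with centimeter
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
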