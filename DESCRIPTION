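Package: wormpath
Title: Single-Worm Tracking, Path Metrics and Levy-Flight Analysis for C. elegans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying Caenorhabditis elegans locomotory behavior from
    single-worm tracker recordings. Segments the worm from grayscale frames
    (Gaussian smoothing, adaptive ratio thresholding, morphological closing,
    largest connected component) and extracts its centroid; re-implements the
    tracker's difference-image localization and virtual camera re-centering loop
    offline; reconstructs globally referenced centroid paths from camera logs;
    computes movement features (speed, acceleration, heading, angular speed),
    grid cell occupancy and the locality index; partitions paths into turning
    events and step lengths; and fits a truncated power law to step lengths by
    maximum likelihood with Kolmogorov-Smirnov based selection of the lower
    cut-off, classifying each path as ballistic, Levy flight or Brownian walk.
    Includes seeded synthetic trajectory simulators and a plate-image renderer so
    the full pipeline can be exercised without recorded video.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
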