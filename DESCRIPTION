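Package: fieldpheno
Title: Point-Cloud Phenotyping of Field Crop Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for single-plant phenotyping of field crop populations
    from colored 3D point clouds. Samples dense point clouds from trained
    Gaussian-splat scene files with Mahalanobis outlier rejection, levels
    and denoises field scenes (RANSAC ground plane, quaternion alignment,
    statistical and bilateral filtering), separates plants from ground with
    a hue-enhanced cloth simulation filter, localizes individual plants by
    density clustering of a bare-stem height layer, segments plant
    instances by region growing under per-plant dynamic spatial
    constraints with overlap-attribution correction, and extracts
    per-plant traits (cotyledon node height, plant height, leaf count and
    leaf area). Includes instance-segmentation evaluation metrics,
    convex-hull point-density metrics, and a seeded synthetic cotton-field
    generator with exact ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RANN,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
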