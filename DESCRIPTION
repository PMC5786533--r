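Package: canopyscan
Title: Terrestrial LiDAR Phenotyping of Row-Crop Canopies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Reconstructs georeferenced 3D canopy point clouds from a
    vehicle-mounted 2D line-scan LiDAR fused with an RTK-GPS position
    stream, segments field plots, removes the ground plane by RANSAC and
    detached weed clusters by Euclidean clustering, and extracts
    plot-level morphologic traits: canopy height percentiles, projected
    canopy area (alpha-shape or grid boundary), and trapezoidal-rule
    plant volume.  Downstream analyses fit three-parameter logistic
    growth curves, interval growth rates, cultivar ANOVA, and
    trait-versus-yield regressions.  A seeded scan simulator over
    analytic canopy solids (hemisphere, ellipsoid cap, box, cone)
    provides closed-form ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
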