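Package: maxsdm
Title: Optimized Maximum-Entropy Species Distribution Modelling and
    Range-Change Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Presence-only species distribution modelling for climate-change
    studies: ESRI ASCII raster I/O and spherical geodesy, occurrence cleaning
    and spatial thinning, Pearson collinearity screening, an L1-penalized
    maximum-entropy engine with linear/quadratic/product/hinge/threshold
    features, feature-class and regularization-multiplier tuning with
    checkerboard spatial cross-validation and AICc selection, threshold-based
    habitat suitability grading with latitude-corrected area accounting,
    scenario-to-scenario range expansion/contraction mapping, and
    distribution-centroid migration kinematics. Includes a synthetic
    climate-landscape generator so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
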