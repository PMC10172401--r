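Package: placentex
Title: Placental Morphometry and Texture Analysis for Volumetric MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extraction of three-dimensional morphometric (mesh volume,
    maternal-to-fetal surface thickness, medial-axis elongation) and
    textural (normalized histogram, gray-level co-occurrence and
    run-length) features from segmented placental MRI volumes, together
    with the longitudinal statistics used to compare pregnancy cohorts:
    generalized estimating equations with robust sandwich covariance,
    least-squares means, per-feature-set false discovery rate control,
    three-step mediation through maternal distress scores, birth-weight
    association models, and per-cohort / spline time-trend models. A
    synthetic-data module generates placenta-like labeled volumes and
    simulated longitudinal cohorts so the full pipeline can be exercised
    and validated without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    igraph,
    lme4,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
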