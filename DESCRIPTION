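Package: geoaccess
Title: Geographic Accessibility of Health Facilities Across Gridded
    Population Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models geographic accessibility to health facilities on a
    friction raster: merges landcover, road and water-barrier layers under
    bridge-priority rules, converts travel scenarios (class speeds) to a
    per-cell crossing-time surface, computes the isotropic
    eight-directional least-cost travel time to the nearest facility, and
    derives accessibility coverage statistics (population within 30, 60,
    ..., 180 minutes) per administrative unit from one or more gridded
    population datasets harmonized with exact mass preservation. Includes
    a synthetic-world generator (clustered settlements, roads, rivers,
    nested admin units) with constrained, uniform-unconstrained and
    covariate-dasymetric population allocation schemes, plus cross-dataset
    comparison statistics: pairwise coverage-difference matrices, per-unit
    average differences, and the association between census-unit size and
    dataset disagreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    rlang,
    sp,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
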