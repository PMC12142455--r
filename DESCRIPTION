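Package: climrisk
Title: Multi-Metric Climate-Change Exposure Analysis for Protected-Area Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-cell climate-change exposure metrics on gridded
    yearly climate data: local (gradient-based) climate velocity, analog
    (distance-based) climate velocity, climate-change magnitude as a
    standardized Euclidean distance, and polygon residence time. Supports
    multi-model ensemble summaries, quartile hotspot/coldspot overlays,
    protected-versus-control comparisons via propensity-score matching with
    covariate-balance diagnostics and paired Wilcoxon tests, and species-level
    exposure aggregation over occupied sites. Includes seeded synthetic-data
    generators (planar climates, confounded protected landscapes, species
    occurrences) with analytically known ground truth, and an end-to-end
    reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ncdf4,
    jsonlite,
    sp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
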