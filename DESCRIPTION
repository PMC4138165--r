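Package: nichedyn
Title: Climatic Niche Dynamics and Reciprocal Distribution Models for
    Biological Invasions
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies how the climatic niche of an introduced species
    changes between its native and invaded ranges. Builds a common
    environmental principal-component space from regional backgrounds,
    converts occurrence records into kernel-smoothed occupancy densities,
    measures niche overlap with Schoener's D together with
    translation-based similarity tests, and decomposes the comparison
    into stability, unfilling and expansion. Also fits a regularized
    maximum-entropy presence/background distribution model, projects it
    reciprocally between ranges, compares thresholded binary ranges, and
    summarises predicted suitability along an altitudinal gradient as
    occupancy profiles. Ships a virtual-species simulator (correlated,
    spatially autocorrelated climate layers; Gaussian niches; suitability
    -weighted occurrence sampling) so every stage can be validated
    against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
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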