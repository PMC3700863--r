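Package: sdmshift
Title: Presence-Only Species Distribution Models and Climate-Driven Range Shifts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for modelling species distributions from
    presence-only occurrence records and monthly climate grids, and for
    quantifying projected range shifts under future climate scenarios.
    Derives the 19 standard bioclimatic variables (BIO1-BIO19) from monthly
    minimum temperature, maximum temperature and precipitation; screens them
    for collinearity by pairwise Pearson correlation; fits an L1-regularized
    maximum-entropy (MaxEnt-style Gibbs) model over background cells with
    linear, quadratic and hinge features; evaluates models with rank-based
    AUC and jackknife variable importance; binarizes suitability with the
    10-percentile training-presence threshold; and stacks species into
    richness maps and range-change summaries (presence overlap, occupied-area
    change, zonal centroids and ellipses, centroid displacement in km, and
    multi-period turnover). A synthetic-data module generates spatially
    autocorrelated climate grids, scenario perturbations and biased
    occurrence samples from a known suitability surface so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    geosphere,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
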