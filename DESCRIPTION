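Package: fucusstatus
Title: Habitat Potential, Depth Zonation and Hurdle Regression for Baltic Fucus Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for assessing the status of brown macroalgae (Fucus spp.)
    from coastal survey data: classification of surveyed sites as potential
    Fucus habitat from hard-substrate cover and a Secchi-depth derived light
    limit, per-water-body occurrence rates with small-sample exclusion,
    detection of the Fucus belt and its lower depth limit on dive transects
    with a substrate-continuation filter, raster point extraction and zonal
    means for environmental covariates, a two-part hurdle model (binomial
    presence/absence plus truncated beta regression for positive occurrence
    rates) with backward pruning of interactions, a log-linear model for the
    lower limit of the Fucus zone with residual diagnostics, and a
    synthetic-data generator emulating a stratified coastal survey design so
    the whole pipeline is testable end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
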