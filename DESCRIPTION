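Package: firelarch
Title: Individual-Based Fire-Vegetation Dynamics for Boreal Larch Forests
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Spatially explicit, individual-based simulation of boreal
    larch forest dynamics coupled to a climate-driven wildfire module.
    Monthly temperature and precipitation are converted into a monthly
    fire probability rating, categorized into mild, severe, and extreme
    fire weather, and aggregated to an annual ignition probability that
    is calibrated to a target mean. Ignitions place circular fires whose
    extent scales with the annual rating and whose per-cell intensity is
    damped by a topographic wetness index. Fire impacts on individual
    trees (stem heating against bark insulation, crown scorch from flame
    height), seed pools, and the insulating litter layer feed back on
    establishment, competition, and active-layer depth. Includes
    synthetic climate and fractal landscape generators, a scenario
    runner for fixed fire-return-interval by fire-intensity experiments
    and one-at-a-time sensitivity runs, and superposed epoch analysis of
    post-fire recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
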