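Package: darkoxygen
Title: Benthic Chamber Oxygen Flux Analysis and Dark Oxygen Production Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for in situ benthic chamber incubations over
    polymetallic nodule fields: oxygen optode calibration (two-point,
    multi-temperature, pressure-corrected) with drift estimation and Winkler
    titration cross-validation; net oxygen change and areal dark oxygen
    production / sediment community oxygen consumption rates from chamber time
    series; diffusive oxygen uptake from porewater microprofiles via Fick's
    first law; a radiolytic oxygen production kinetic model from radionuclide
    inventories; quantitative screening of incubation artifacts (chamber
    plastic intrusion, trapped air bubbles, core-tube leaks); and
    electrochemical feasibility statistics for the seawater-electrolysis
    hypothesis (nodule surface voltage surveys, oxygen evolution reaction
    thresholds, one-way ANOVA and Spearman correlations). Includes a
    synthetic-data generator that emulates the statistical structure of the
    field campaign so every stage is testable without cruise data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
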