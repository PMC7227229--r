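Package: nfertghg
Title: Greenhouse Gas Inventory for Synthetic Nitrogen Fertilizer
    Manufacture and Field Application
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An emission-factor (IPCC-style) greenhouse gas inventory for
    synthetic nitrogen fertilizer use on upland wheat and maize. Computes
    per-product manufacture emissions (kg CO2-eq per kg fertilizer-N),
    region- and crop-specific direct soil N2O emissions, CO2-equivalent
    totals under a configurable N2O global warming potential, and area-
    and yield-scaled emission intensities from provincial activity tables
    (sown area, grain yield, per-product N application rates). Provides
    stratified province-to-region-to-national aggregation with interannual
    mean and standard deviation, percentage shares, application-rate-class
    area fractions, report tables, a seeded synthetic activity-data
    generator, and an embedded fixture of published Chinese national and
    provincial benchmark values for reconciliation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
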