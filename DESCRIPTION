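Package: grapeheat
Title: Thermal-Time Modelling and Harvest Forecasting for Table Grape
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for heat-unit (growing degree day) analysis of grapevine
    phenology. Computes hourly growing degree days with lower and upper
    cardinal-temperature capping, estimates base and upper threshold
    temperatures by five classical criteria (least SD in GDD, least SD in
    days, least CV in GDD, regression coefficient, x-intercept) and by
    coefficient-of-variation scans, derives heat-unit requirements between
    phenological stages (BBCH 09 bud break, 65 full bloom, 89 harvest), and
    forecasts harvest dates by projecting requirements onto observed or
    reference (average/typical meteorological) years, with a calendar-day
    baseline for comparison. Includes a synthetic hourly weather and
    phenology generator with known ground truth for validation, and
    transcribed reference tables for the 'Flame Seedless' cultivar grown in
    open field and plastic greenhouse at El Ejido (Almeria, Spain).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
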