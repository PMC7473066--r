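Package: nutribca
Title: Benefit-Cost Analysis of an Early-Childhood Nutrition Package
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the economic evaluation of a scaled-up package of ten
    early-childhood nutrition interventions in Haiti. Converts annual schedules
    of avoided deaths, diarrhea episodes and stunting cases into monetized
    benefit streams under alternative mortality valuations (value of a
    statistical life transferred with an income elasticity, value of a
    statistical life year, and GNI-per-capita multiplier variants) and
    morbidity valuations (willingness-to-pay benefit transfer and monetized
    years lived with disability plus third-party costs), builds the scale-up
    cost stream with labor-cost growth, models lifetime earnings gains from
    avoided stunting, and assembles annualized benefit-cost ratios and net
    benefits with valuation-bound and Monte Carlo uncertainty analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
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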