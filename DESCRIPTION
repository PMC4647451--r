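Package: medflora
Title: Quantitative Analysis of Medicinal-Plant Utilization Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative ethnobotany built around a coded
    medicinal-plant survey from four study areas of East Sepik Province,
    Papua New Guinea. Parses and validates coded remedy reports, computes
    per-area usage profiles and shared/unique taxa, and classifies plant
    families as medicinally over- or under-utilized relative to a regional
    flora or traditional-medicines database using Bayesian binomial
    credible intervals (uniform prior). Includes a seeded synthetic survey
    generator so the classifier's operating characteristics can be
    estimated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
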