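Package: popfusion
Title: Urban Population Microsimulation by Calibration Reweighting and
    Statistical Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for static-ageing microsimulation of an urban population:
    clone a household-structured census sample, calibrate person weights to
    demographic benchmark tables with a bounded generalised-regression (GREG)
    estimator, project benchmark tables forward with geometric growth rules,
    statistically match an administrative medical-insurance file onto the
    census file within demographic cell groups by minimal age distance, and
    impute monthly incomes by stratified donor sampling. Includes a synthetic
    household-microdata generator so the full pipeline is testable without
    confidential microdata, plus family-income quintile summaries and
    population-group reports for medical-insurance coverage analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
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
    withr,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
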