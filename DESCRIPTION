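Package: overwintr
Title: Harmonic Air-Water Temperature Transfer and Blue Crab Overwinter
    Survival Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for projecting estuarine overwintering conditions from
    long daily temperature records. Fits trend-plus-harmonic regression
    models to daily air and water temperature, builds an air-to-water
    transfer function from calibration coefficient ratios, projects daily
    water temperature to 2100 under an extended-trend scenario (with
    parameter-resampling uncertainty) and under an ensemble of
    downscaled-GCM-like air temperature members, converts projected
    temperature into per-winter dormancy duration and severity for blue
    crab (days below the 9 degree Celsius critical temperature for
    growth), and evaluates a Weibull accelerated-failure-time overwinter
    survival model. Includes gap filling and characterisation for
    observational records and a synthetic daily-climate generator with
    known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
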