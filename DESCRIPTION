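Package: foodcast
Title: Forecastability of Sub-National Food Insecurity from Survey Indicators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how far ahead the daily prevalence of insufficient
    food consumption can be forecast at sub-national level. Builds daily
    area-level prevalence series from household survey microdata (Food
    Consumption Score and reduced Coping Strategy Index) via weighted rolling
    windows, quantifies the intrinsic predictability of those series with
    permutation entropy, and fits horizon-specific gradient-boosted forecasting
    models (1 to 30 days ahead) benchmarked against a naive persistence
    baseline, including learning-curve analyses versus training-set size. A
    seeded synthetic-data generator emulating conflict, weather, price and
    Ramadan driven prevalence dynamics makes the whole pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    zoo,
    stats,
    utils,
    tools,
    xgboost,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
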