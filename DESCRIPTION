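Package: ringmap
Title: Sensor-Network Cleaning, Gap Imputation and Concentric-Region
    Exposure Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for turning sparse networks of environmental monitoring
    stations (air quality, meteorology, pollen) into complete regional
    exposure surfaces. Provides rule-based cleaning of raw hourly sensor
    series, relative-humidity derivation from air and dewpoint temperature,
    iterative multivariate gap imputation driven by nearest reference
    stations (Bayesian ridge regression with distribution-normalising
    transforms), daily aggregation with imputed-fraction flags, and the
    concentric-regions algorithm: each region-day value is the mean of
    sensor values found in the smallest nonempty ring of adjacent regions,
    with the ring count reported as a confidence proxy. Includes a
    leave-one-sensor-out and data-removal validation harness and a
    synthetic-data generator so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    geosphere,
    stats,
    utils
Suggests:
    car,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
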