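Package: waterbal
Title: Daily Thornthwaite-Type Water Balance, Climatic Water Deficit and
    Change-Vector Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A daily, gridded Thornthwaite-type water balance model for
    ecohydrological analysis. Partitions precipitation into rain and snow,
    accumulates and melts snow water equivalent with a degree-day scheme,
    computes potential evapotranspiration from temperature with the Oudin
    equation (daily solar declination, FAO-56 extraterrestrial radiation)
    adjusted for terrain heat loading, routes water through an
    NDVI-adjusted Thornthwaite-Mather soil bucket, and reports actual
    evapotranspiration, climatic water deficit, soil water, snow water
    equivalent and runoff. Includes per-pixel least-squares trend analysis
    with a normalized per-decade change index, two-period bivariate
    AET:CWD change vectors with Euclidean intensity and direction classes,
    equal-count bivariate zone classification, snow-phenology metrics over
    water years, and a seeded synthetic forcing generator so the whole
    pipeline is testable without external data.
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
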