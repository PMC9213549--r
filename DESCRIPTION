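Package: fluxiso
Title: Daily Isotope Ratios of Precipitation, Evapotranspiration and
    Ecosystem Exchange
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical downscaling of biweekly precipitation-composite
    stable water isotope ratios (d2H, d18O) to daily resolution with a
    Gaussian copula conditioned on daily precipitation amounts, and
    Miller-Tans mixing-model estimation of the daily isotope ratio of
    evapotranspiration (d2H, d18O) and net ecosystem exchange (d13C)
    from multi-height tower profiles.  Includes the full quality-flag
    scheme and wide-matrix CSV file layout used by published daily
    flux-isotope data products, a ground-truthed synthetic-data
    generator for both input families, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
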