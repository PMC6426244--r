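Package: nitrifyr
Title: Seasonal 15N-Tracer Nitrification Rates in Ice-Covered Lakes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidy pipeline for estimating in-situ ammonia-oxidation (AO)
    rates from single end-point 15N-NH4+ tracer incubations in seasonally
    ice-covered lakes, together with the surrounding measurement chain:
    isotope-standard calibration and delta/atom-fraction conversion for the
    azide (nitrite to N2O) method, tracer-spike design rules and over-spike
    quality flags, Monte-Carlo uncertainty propagation at stated analytical
    precisions, dissolved-N2O back-calculation from headspace equilibration,
    monochromatic (Lorenzen) chlorophyll-a, and an environmental-drivers
    analysis (Kruskal-Wallis with Dunn-Holm letters, paired t,
    forward-selection multiple regression, and cross-validated univariate
    regression trees). A seeded synthetic generator forward-simulates tracer
    incubations and an annual under-ice lake time series so that every stage
    of the pipeline is verifiable against planted truths.
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
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
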