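Package: mosqtherm
Title: Thermal Performance, Cold Tolerance and Voltinism Modelling for
    Container-Breeding Mosquitoes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing temperature-dependence of mosquito life
    history from laboratory rearing experiments. Fits exposure-duration
    response curves (exponential or logistic, selected by AIC) to egg
    cold-exposure hatch data and reports asymptotic minimal hatch success;
    summarises per-temperature life-trait parameters with the associated
    ANOVA, t-test and exact binomial sex-ratio tests; fits a candidate zoo
    of thermal performance models to cumulative female survival and
    extracts cardinal temperatures from the Briere-1 model; converts the
    age-at-emergence fit into a generation-time function and accumulates
    potential generations per year over monthly temperature grids; and
    counts multi-day frost events in daily temperature series. A synthetic
    data module generates all input kinds with the statistical structure
    the analysis assumes, so the full pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
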