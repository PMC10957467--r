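Package: fctcitsa
Title: Interrupted Time Series Analysis of Tobacco Control Treaty Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-time interrupted time series analysis (ITSA) of national
    smoking trajectories around ratification of a tobacco-control treaty.
    Realigns country-year panels of current, former and ever smokers to event
    time around each country's ratification year, aggregates them into country
    groups (world, income, tax-change), fits five segmented polynomial trend
    models by ordinary least squares with Newey-West
    heteroskedasticity-and-autocorrelation-consistent standard errors, selects
    among them by AIC, and converts the selected fit into average
    pre-ratification trends, average post-ratification trend changes and
    cumulative effects with delta-method confidence intervals. Projects the
    pre-ratification trend forward to quantify averted smokers and additional
    quitters, and bootstraps countries for uncertainty. A synthetic-data
    generator with known ground truth makes every stage testable without
    external data.
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
    sandwich,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
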