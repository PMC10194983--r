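Package: excesstrend
Title: Excess-Trend Decomposition of Annual Vital-Statistics Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models long-run declines in infant-mortality and stillbirth rates as a
    smooth secular trend (floored-logistic or exponential-polynomial in time) with
    superimposed lognormal-density excess terms, fitted by iteratively reweighted
    nonlinear least squares with binomial variances. Provides stepwise excess-term
    selection with overdispersion-scaled F-tests, profile-likelihood confidence
    intervals, windowed observed/expected excess-death estimation with slope-fixed
    refit intervals, peak-timing extraction from the lognormal mode, Poisson
    log-linear trend fits with window exclusion, and a synthetic-data generator
    with binomial or beta-binomial noise for validation studies.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
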