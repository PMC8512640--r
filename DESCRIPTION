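Package: rbsarmax
Title: Birnbaum-Saunders Autoregressive Moving Average Models with Regressors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits dynamic regression models for positive, right-skewed time
    series in which the response, conditional on its past, follows the
    mean-parameterized (reparameterized) Birnbaum-Saunders distribution and
    the conditional mean carries an ARMA recursion plus exogenous regressors
    (the RBSARMAX model). Provides the reparameterized Birnbaum-Saunders
    distribution (density, distribution function, quantiles, random
    generation, moments), conditional maximum-likelihood estimation with
    numerical standard errors, one-step fitted values and multi-step
    forecasts, generalized Cox-Snell and randomized quantile residuals with
    simulated envelopes, simulators for correctly specified and
    Weibull-misspecified data-generating processes, a Gaussian ARMAX
    baseline, and a Monte Carlo harness for estimator bias/MSE and model
    comparison studies. Tidy methods (tidy(), glance(), augment()) and
    ggplot2-based diagnostics are included throughout.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
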