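Package: demandcast
Title: Hybrid ARIMA and Self-Adaptive Filtering Forecasting of Healthcare Demand
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for short- and medium-term forecasting of univariate
    healthcare demand series such as daily outpatient visits. Implements the
    Box-Jenkins workflow (differencing-order choice via an augmented
    Dickey-Fuller test, Ljung-Box white-noise checks, BIC grid order selection,
    conditional-least-squares ARMA estimation, rolling one-step forecasting)
    together with a least-mean-squares adaptive-filter forecaster and a hybrid
    refiner that treats estimated ARMA coefficients as adaptive-filter weights
    and adjusts them by steepest descent on the one-step prediction error.
    Includes seeded generators for synthetic outpatient-visit series with
    weekly cyclicity, trend and holiday dips, forecast-error metrics
    (MAPE, PE dispersion, RMSE, MAE, correlation), and a reproducible
    end-to-end pipeline with file-based artifacts.
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
    utils,
    yaml
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
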