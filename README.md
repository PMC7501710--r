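# demandcast

Forecasting tools for univariate healthcare-demand series — daily outpatient
or emergency-department visit counts — aimed at analysts who plan staffing
and resources from short histories of a single registry series.

The package implements a hybrid of two classical forecasters:

1. **Box–Jenkins ARIMA.** The series is differenced `d` times until an
   augmented Dickey–Fuller test supports stationarity, checked against white
   noise with a Ljung–Box test, and an ARMA(p, q) model

   `y_t = φ0 + φ1 y_{t−1} + … + φp y_{t−p} + ε_t − θ1 ε_{t−1} − … − θq ε_{t−q}`

   is selected from a BIC grid and estimated by conditional least squares.

2. **Self-adaptive filtering (LMS).** The estimated coefficients
   `(φ1..φp, θ1..θq)` are treated as adaptive-filter weights over the
   regressor `(y_{t−1},…,y_{t−p}, −ε_{t−1},…,−ε_{t−q})` and refined by
   steepest-descent updates `w' = w + 2 k e_t z_t` swept repeatedly over the
   training data, with the learning constant bounded by
   `k ≤ 1 / max Σ x_i²`. Rounds stop when the round mean absolute error
   converges.

Both the plain and the refined model then produce rolling one-step forecasts
over a verification window and are compared by MAPE, the PE extremes and
dispersion, RMSE, MAE and the correlation coefficient. A standalone
adaptive-filter forecaster (weighted moving average with LMS updates) and a
seeded synthetic outpatient-series generator (weekly profile, trend, holiday
closures, Gaussian noise) round out the toolkit.

## Worked example

```r
library(demandcast)

# a year-and-a-quarter of synthetic daily visits; weekday analysis set,
# first week dropped, 283 training / 22 verification points
daily <- simulate_outpatient(n_days = 441, seed = 1)
wk    <- remove_weekends(daily)[-(1:5), ][1:305, ]
sp    <- split_series(wk, train_size = 283)

res <- hybrid_pipeline(sp$train, sp$verify, adf_variant = "constant")
res
#> Hybrid pipeline: d = 0, selected ARIMA(3, 0, 5), 100 refinement round(s)
#> # A tibble: 2 x 9
#>   model  pe_max pe_min  mape sigma_pe  rmse   mae     r n_used
#>   <chr>   <dbl>  <dbl> <dbl>    <dbl> <dbl> <dbl> <dbl>  <int>
#> 1 arima    16.2  0.238  8.39     5.08  17.6  15.3 0.666     22
#> 2 hybrid   21.3  0.872  8.81     5.62  19.4  16.3 0.630     22

tidy(res$refit)[1:4, ]
#> # A tibble: 4 x 3
#>   term       before    after
#>   <chr>       <dbl>    <dbl>
#> 1 constant 163.     163.
#> 2 ar1        0.993    0.997
#> 3 ar2       -1.23    -1.22
#> 4 ar3        0.374    0.365
```

Reading the output: the ADF test (constant variant, appropriate for a
positive-level series) accepts the undifferenced series, the BIC grid picks
ARIMA(3, 0, 5), and the refinement sweeps nudge the coefficients while
lowering the online training MAE. Over this 22-day holdout the plain model's
rolling one-step MAPE is 8.39% against the refined model's 8.81% — on
fixtures whose seasonal mean is deterministic, the least-squares fit is
already near-optimal and refinement mainly adds jitter; see the methods
vignette (`vignettes/hybrid-demand-forecasting.Rmd`) for when the refinement
does and does not help. `autoplot(res)` draws the three verification-window
trajectories, `autoplot(res$refit)` the round-MAE convergence.

A thin command-line wrapper over the same pipeline lives at
`inst/cli/demandcast.R`:

```sh
Rscript inst/cli/demandcast.R --input visits.csv --train-size 283 --seed 7 --out run1
```

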