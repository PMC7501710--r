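test_that("sample ACF and PACF behave as theory predicts", {
  expect_equal(acf_series(rnorm(50), 5)$acf[1], 1)
  x <- sim_arma_vec(5000, phi = 0.6, seed = 14)
  expect_equal(acf_series(x, 3)$acf[2], 0.6, tolerance = 0.05)
  # white noise: most autocorrelations inside the 3/sqrt(n) band
  wn <- sim_arma_vec(2000, seed = 15)
  rho <- acf_series(wn, 40)$acf[-1]
  expect_gte(mean(abs(rho) < 3 / sqrt(2000)), 0.95)
  expect_error(acf_series(rep(2, 30), 5), class = "dc_undefined_metric")
  pc <- pacf_series(x, 10)
  expect_equal(pc$pacf[1], 0.6, tolerance = 0.05)
  expect_lt(max(abs(pc$pacf[5:10])), 0.1)
})

test_that("information criterion follows the penalized log-likelihood formulas", {
  expect_equal(information_criterion(0, 2, exp(2), "bic"), 4)
  expect_equal(information_criterion(0, 2, 100, "aic"), 4)
  expect_equal(information_criterion(-100, 3, 100, "bic"), 200 + 3 * log(100))
  expect_error(information_criterion(0, 5, 3), class = "dc_invalid_argument")
})

test_that("CSS estimation is exact on a noise-free AR(1) decay", {
  fit <- suppressWarnings(estimate_arima(c(8, 4, 2, 1, 0.5), p = 1, include_constant = FALSE))
  expect_equal(fit$phi, 0.5, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)
})

test_that("CSS recovers ARMA(1,1) parameters and a drifted AR(1) constant", {
  ok <- 0L
  for (seed in 1:5) {
    y <- sim_arma_vec(2000, phi = 0.5, theta = 0.7, seed = seed)
    f <- estimate_arima(y, p = 1, q = 1, include_constant = FALSE)
    if (abs(f$phi - 0.5) < 0.1 && abs(f$theta - 0.7) < 0.1) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
  # x_t = 1 + 0.5 x_{t-1} + e
  yd <- sim_arma_vec(5000, phi = 0.5, phi0 = 1, seed = 31)
  fd <- estimate_arima(yd, p = 1, include_constant = TRUE)
  expect_equal(fd$phi0, 1, tolerance = 0.15)
  expect_equal(fd$phi, 0.5, tolerance = 0.05)
})

test_that("pure AR CSS estimates equal ordinary least squares on the lag matrix", {
  for (seed in 1:3) {
    y <- sim_arma_vec(400, phi = c(0.5, -0.3), seed = 100 + seed)
    f <- estimate_arima(y, p = 2, include_constant = FALSE)
    Z <- embed(y, 3)
    ols <- unname(coef(lm(Z[, 1] ~ Z[, 2] + Z[, 3] - 1)))
    expect_equal(f$phi, ols, tolerance = 1e-6)
  }
})

test_that("CSS estimates agree with an independent reference implementation", {
  for (seed in 1:3) {
    y <- sim_arma_vec(1500, phi = 0.5, theta = 0.7, seed = 200 + seed)
    f <- estimate_arima(y, p = 1, q = 1, include_constant = FALSE)
    ref <- stats::arima(y, order = c(1, 0, 1), include.mean = FALSE, method = "CSS")
    expect_equal(f$phi, unname(coef(ref)["ar1"]), tolerance = 0.05)
    # reference uses the opposite MA sign convention
    expect_equal(f$theta, -unname(coef(ref)["ma1"]), tolerance = 0.05)
  }
})

test_that("model innovations reduce to the series under the identity model", {
  y <- sim_arma_vec(100, seed = 4)
  m <- manual_arima(y)
  expect_equal(model_residuals(m)$residual, y)
  # noise-free AR(1): residuals vanish after warm-up
  dec <- manual_arima(c(8, 4, 2, 1, 0.5, 0.25), phi = 0.5)
  expect_lt(max(abs(model_residuals(dec)$residual[-1])), 1e-12)
  # white-noise residual variance tracks the series variance under (0,0,0)
  wn <- sim_arma_vec(2000, seed = 41)
  expect_equal(var(model_residuals(manual_arima(wn))$residual), var(wn), tolerance = 0.01)
})

test_that("one-step forecasts follow the ARMA recursion exactly", {
  # AR(1) with constant: 1 + 0.5 * 4 = 3
  m1 <- manual_arima(c(1, 2, 4), phi0 = 1, phi = 0.5)
  expect_equal(forecast_arima(m1, 1, "recursive")$forecast, 3)
  # ARMA(1,1): 0.5 * 4 - 0.3 * eps_last with eps forced to 1 by construction
  hist <- c(0, 1)
  m2 <- manual_arima(hist, phi = 0.5, theta = 0.3)
  # innovations: eps_1 = 0 (conditioned), eps_2 = 1 - 0.5*0 - (-0.3*0) = 1
  expect_equal(forecast_arima(m2, 1, "recursive")$forecast, 0.5 * 1 - 0.3 * 1)
  m3 <- manual_arima(c(32, 16, 8), phi = 0.5)
  expect_equal(forecast_arima(m3, 3, "recursive")$forecast, c(4, 2, 1))
  expect_error(forecast_arima(m3, 2, "rolling"), class = "dc_invalid_argument")
})

test_that("rolling one-step training errors equal the residual recursion", {
  y <- sim_arma_vec(300, phi = 0.6, theta = 0.4, seed = 55)
  f <- estimate_arima(y, p = 1, q = 1, include_constant = FALSE)
  n0 <- 150L
  prefix <- manual_arima(y[seq_len(n0)], phi0 = f$phi0, phi = f$phi, theta = f$theta)
  fc <- forecast_arima(prefix, length(y) - n0, "rolling", actuals = y[(n0 + 1):length(y)])
  full <- model_residuals(f)
  expect_equal(fc$actual - fc$forecast, full$residual[(n0 + 1):length(y)], tolerance = 1e-10)
})

test_that("rolling forecasts undifference correctly for d = 1", {
  set.seed(66)
  x <- cumsum(rnorm(120)) + 50
  f <- estimate_arima(x, p = 1, d = 1, q = 0, include_constant = FALSE)
  hist <- x[1:100]
  m <- manual_arima(hist, phi = f$phi, d = 1L)
  fc <- forecast_arima(m, 1, "rolling", actuals = x[101])
  manual <- hist[100] + f$phi * (hist[100] - hist[99])
  expect_equal(fc$forecast, manual, tolerance = 1e-10)
})

test_that("order selection returns the documented grid shape and parsimonious picks", {
  y <- sim_arma_vec(500, phi = 0.5, theta = 0.7, seed = 7)
  g <- select_order(y, max_p = 2, max_q = 2, include_constant = FALSE)
  expect_equal(dim(g$criterion_matrix), c(3L, 3L))
  expect_true(is.finite(g$criterion_matrix[g$selected_p + 1, g$selected_q + 1]))
  expect_equal(min(g$criterion_matrix),
               g$criterion_matrix[g$selected_p + 1, g$selected_q + 1])
  # white noise: criterion penalty keeps the chosen order tiny
  picks <- sapply(1:5, function(s) {
    wn <- sim_arma_vec(300, seed = 300 + s)
    g <- select_order(wn, max_p = 2, max_q = 2)
    g$selected_p + g$selected_q
  })
  expect_gte(mean(picks <= 1), 0.8)
})

test_that("adding parameters never increases the conditional RSS", {
  y <- sim_arma_vec(400, phi = 0.5, theta = 0.7, seed = 90)
  f1 <- estimate_arima(y, p = 1, q = 1, include_constant = FALSE)
  f2 <- estimate_arima(y, p = 2, q = 1, include_constant = FALSE)
  expect_lte(f2$rss, f1$rss * (1 + 1e-8))
})

test_that("near-unit-root estimates warn instead of failing", {
  expect_warning(warn_unit_roots <- demandcast:::warn_unit_roots(0.9993, numeric(0)))
})

test_that("the order grid enumerates p and q from 0 to the bound (7x7 at bound 6)", {
  cells <- demandcast:::order_cells(6, 6)
  expect_identical(nrow(cells), 49L)
  expect_identical(range(cells$p), c(0L, 6L))
  expect_identical(range(cells$q), c(0L, 6L))
})
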