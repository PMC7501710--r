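test_that("regressor vector carries lags and negated innovations", {
  expect_equal(regressor_vector(c(2, 4), c(0.5, 1), t = 3, p = 1, q = 1), c(4, -1))
  expect_equal(regressor_vector(c(1, 2, 3), c(0, 0, 0), t = 3, p = 2, q = 0), c(2, 1))
  expect_error(regressor_vector(c(1, 2), c(0, 0), t = 1, p = 1, q = 1),
               class = "dc_invalid_argument")
})

test_that("phi0 + weights . regressor equals the model's one-step predictor exactly", {
  y <- sim_arma_vec(200, phi = 0.6, theta = 0.4, seed = 70)
  f <- estimate_arima(y, p = 1, q = 1, include_constant = TRUE)
  res <- model_residuals(f)
  w <- c(f$phi, f$theta)
  for (t in c(3, 50, 200)) {
    z <- regressor_vector(y, res$residual, t, 1, 1)
    expect_equal(f$phi0 + sum(w * z), res$fitted[t], tolerance = 1e-12)
  }
})

test_that("refinement with k = 0 or max_rounds = 0 leaves parameters untouched", {
  y <- sim_arma_vec(300, phi = 0.5, theta = 0.7, seed = 81)
  f <- estimate_arima(y, p = 1, q = 1, include_constant = FALSE)
  r0 <- refine_arima(f, k = 0, max_rounds = 5)
  expect_identical(r0$after$phi, f$phi)
  expect_identical(r0$after$theta, f$theta)
  rn <- refine_arima(f, max_rounds = 0)
  expect_identical(rn$rounds_run, 0L)
  expect_identical(rn$after$phi, f$phi)
})

test_that("an exact model is a fixed point of refinement", {
  dec <- 8 * 0.5^(0:9)
  m <- manual_arima(dec, phi = 0.5)
  r <- refine_arima(m, max_rounds = 10)
  expect_true(r$converged)
  expect_identical(r$rounds_run, 1L)
  expect_equal(r$after$phi, 0.5, tolerance = 1e-12)
  expect_lt(r$trace$mae[1], 1e-10)
})

test_that("refinement descends from perturbed coefficients toward the truth", {
  closer <- logical(6)
  for (i in seq_along(closer)) {
    y <- sim_arma_vec(500, phi = 0.6, theta = -0.5, seed = 500 + i)
    m <- manual_arima(y, phi = 0.6 + 0.4 * (-1)^i, theta = -0.5 - 0.4 * (-1)^i)
    r <- suppressWarnings(refine_arima(m, max_rounds = 100))
    expect_lte(utils::tail(r$trace$mae, 1), r$trace$mae[1] + 1e-9)
    d0 <- abs(m$phi - 0.6) + abs(m$theta + 0.5)
    d1 <- abs(r$after$phi - 0.6) + abs(r$after$theta + 0.5)
    closer[i] <- d1 < d0
  }
  expect_gte(sum(closer), 5L)
})

test_that("frozen-residual refinement is available as a sensitivity mode", {
  y <- sim_arma_vec(300, phi = 0.6, theta = -0.5, seed = 83)
  m <- manual_arima(y, phi = 0.2, theta = -0.1)
  r <- suppressWarnings(refine_arima(m, max_rounds = 20, residual_mode = "frozen"))
  expect_s3_class(r, "hybrid_refit")
  expect_lte(utils::tail(r$trace$mae, 1), r$trace$mae[1] + 1e-9)
})

test_that("the pipeline returns paired metrics and respects max_rounds = 0", {
  sp <- weekday_split(seed = 1)
  res <- suppressWarnings(
    hybrid_pipeline(sp$train, sp$verify, max_p = 2, max_q = 2, max_rounds = 0)
  )
  expect_identical(sort(res$metrics$model), c("arima", "hybrid"))
  expect_equal(res$metrics$mape[res$metrics$model == "arima"],
               res$metrics$mape[res$metrics$model == "hybrid"])
  expect_identical(res$refit$rounds_run, 0L)
  expect_identical(nrow(res$forecasts), 22L)
})

test_that("rolling forecasts of a self-consistent verify window give zero MAPE", {
  y <- sim_arma_vec(260, phi = 0.6, theta = -0.3, seed = 91)
  f <- estimate_arima(y[1:200], p = 1, q = 1)
  rec <- forecast_arima(f, 30, "recursive")
  roll <- forecast_arima(f, 30, "rolling", actuals = rec$forecast)
  expect_equal(roll$forecast, rec$forecast, tolerance = 1e-10)
  expect_equal(forecast_metrics(rec$forecast, roll$forecast)$mape, 0, tolerance = 1e-10)
})

test_that("refinement on admissible k never ends above its starting training error", {
  worse <- 0L
  for (seed in 1:10) {
    y <- sim_arma_vec(400, phi = 0.7, theta = -0.4, seed = 700 + seed)
    m <- manual_arima(y, phi = 0.4, theta = -0.1)
    r <- suppressWarnings(refine_arima(m, max_rounds = 50))
    if (utils::tail(r$trace$mae, 1) > r$trace$mae[1] + 1e-9) worse <- worse + 1L
  }
  expect_identical(worse, 0L)
})
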