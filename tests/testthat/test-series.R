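test_that("differencing matches hand-computed examples and rejects bad orders", {
  expect_equal(difference_series(c(1, 3, 6, 10), 1)$value, c(2, 3, 4))
  expect_equal(difference_series(c(5, 5, 5, 5), 1)$value, c(0, 0, 0))
  expect_equal(difference_series(c(1, 3, 6, 10), 2)$value, c(1, 1))
  expect_equal(difference_series(c(1, 3, 6, 10), 0)$value, c(1, 3, 6, 10))
  expect_error(difference_series(c(1, 2), 2), class = "dc_invalid_argument")
})

test_that("undifferencing inverts differencing for d in 0..2", {
  expect_equal(undifference_series(c(2, 3, 4), pre_sample = 1)$value, c(3, 6, 10))
  expect_equal(nrow(undifference_series(numeric(0), pre_sample = 7)), 0L)
  for (d in 1:2) {
    for (seed in 1:5) {
      set.seed(seed)
      x <- cumsum(rnorm(50))
      dx <- difference_series(x, d)$value
      rec <- undifference_series(dx, pre_sample = x[seq_len(d)])$value
      expect_equal(rec, x[-seq_len(d)], tolerance = 1e-9)
    }
  }
})

test_that("percentage errors follow |a - p| / |a| * 100 and exclude zero actuals", {
  expect_equal(percentage_errors(c(100, 200), c(90, 210))$pe, c(10, 5))
  expect_equal(percentage_errors(c(3, 7, 9), c(3, 7, 9))$pe, c(0, 0, 0))
  pe <- percentage_errors(c(50, 0, 50), c(55, 1, 45))
  expect_equal(pe$pe, c(10, NA, 10))
  expect_identical(attr(pe, "n_excluded"), 1L)
  expect_identical(attr(pe, "n_used"), 2L)
  expect_error(percentage_errors(c(0, 0), c(1, 2)), class = "dc_undefined_metric")
})

test_that("metric summary reproduces hand-computed values and edge cases", {
  m <- forecast_metrics(c(100, 200, 400), c(90, 210, 400))
  expect_equal(m$mape, 5)
  expect_equal(m$pe_max, 10)
  expect_equal(m$pe_min, 0)
  expect_equal(m$sigma_pe, sd(c(10, 5, 0)))

  ident <- forecast_metrics(c(3, 7, 9), c(3, 7, 9))
  expect_equal(ident$mape, 0)
  expect_equal(ident$rmse, 0)
  expect_equal(ident$mae, 0)
  expect_equal(ident$r, 1)

  shift <- forecast_metrics(c(10, 20, 35), c(10, 20, 35) + 3)
  expect_equal(shift$r, 1)
  expect_equal(shift$mae, 3)

  expect_warning(z <- forecast_metrics(c(5, 5, 5), c(4, 6, 5)))
  expect_true(is.na(z$r))
})

test_that("PE-based metrics are scale invariant and rmse >= mae always", {
  for (seed in 1:10) {
    set.seed(seed)
    a <- runif(30, 50, 150)
    p <- a + rnorm(30, 0, 10)
    m1 <- forecast_metrics(a, p)
    m2 <- forecast_metrics(7.3 * a, 7.3 * p)
    expect_equal(m1[c("pe_max", "pe_min", "mape", "sigma_pe")],
                 m2[c("pe_max", "pe_min", "mape", "sigma_pe")], tolerance = 1e-12)
    expect_gte(m1$rmse, m1$mae)
    # raw-error metrics are symmetric in the pair
    m3 <- forecast_metrics(p, a)
    expect_equal(m3$rmse, m1$rmse)
    expect_equal(m3$mae, m1$mae)
  }
})

test_that("series constructor validates lengths, finiteness and date order", {
  s <- series_tbl(c(1, 2), date = as.Date("2020-01-01") + 0:1)
  expect_named(s, c("date", "value"))
  expect_error(series_tbl(numeric(0)), class = "dc_invalid_argument")
  expect_error(series_tbl(c(1, Inf)), class = "dc_invalid_argument")
  expect_error(series_tbl(c(1, 2), date = as.Date(c("2020-01-02", "2020-01-01"))),
               class = "dc_invalid_argument")
})

test_that("series splitting respects counts and fractions", {
  sp <- split_series(1:10, 0.8)
  expect_equal(nrow(sp$train), 8L)
  expect_equal(nrow(sp$verify), 2L)
  sp2 <- split_series(1:305, 283L)
  expect_equal(nrow(sp2$train), 283L)
  expect_equal(nrow(sp2$verify), 22L)
  expect_error(split_series(1:5, 5L), class = "dc_invalid_argument")
})
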