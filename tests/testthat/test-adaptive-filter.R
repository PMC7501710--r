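test_that("initial weights are the equal-weight moving average", {
  expect_equal(init_weights(4), rep(0.25, 4))
  expect_equal(init_weights(1), 1)
  for (N in c(2, 5, 9)) expect_equal(sum(init_weights(N)), 1)
  expect_error(init_weights(0), class = "dc_invalid_argument")
})

test_that("learning bound follows the reciprocal sum-of-squares rule", {
  expect_equal(learning_bound(c(3, 4)), 1 / 25)
  expect_equal(learning_bound(c(1, 2, 3), window = "sliding", N = 2), 1 / 13)
  x <- c(2, -1, 4, 3)
  expect_equal(learning_bound(5 * x), learning_bound(x) / 25)
  expect_error(learning_bound(rep(0, 10)), class = "dc_invalid_argument")
})

test_that("the LMS update is the exact steepest-descent step", {
  expect_equal(lms_update(c(0.5, 0.5), 0.01, 2, c(1, 2)), c(0.54, 0.58))
  w <- c(0.2, -0.1, 0.4)
  expect_equal(lms_update(w, 0.05, 0, c(1, 2, 3)), w)
  expect_equal(lms_update(w, 0, 5, c(1, 2, 3)), w)
  expect_error(lms_update(c(1, 2), 0.1, 1, c(1, 2, 3)), class = "dc_invalid_argument")
})

test_that("the update equals the negative finite-difference gradient of e^2", {
  set.seed(77)
  for (i in 1:25) {
    N <- sample(2:5, 1)
    w <- rnorm(N)
    win <- rnorm(N, sd = 2)
    target <- rnorm(1, sd = 2)
    err <- function(wv) (target - sum(wv * win))^2
    num_grad <- vapply(seq_len(N), function(j) {
      h <- 1e-6
      wp <- w; wp[j] <- wp[j] + h
      wm <- w; wm[j] <- wm[j] - h
      (err(wp) - err(wm)) / (2 * h)
    }, numeric(1))
    e <- target - sum(w * win)
    analytic <- 2 * e * win          # the update direction at k = 1
    expect_equal(analytic, -num_grad, tolerance = 1e-5)
  }
})

test_that("equal frozen weights reproduce the simple moving average exactly", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- runif(40, 10, 50)
    N <- sample(2:6, 1)
    state <- list(weights = init_weights(N), series = x)
    pred <- predict_adaptive_filter(state, 1, "recursive")$forecast
    expect_identical(pred, mean(x[(length(x) - N + 1):length(x)]))
  }
  # persistence weights return the last observation
  state <- list(weights = c(1, 0, 0), series = c(5, 9, 13))
  expect_equal(predict_adaptive_filter(state, 1, "recursive")$forecast, 13)
  # equal weights over (3, 6, 9) -> 6
  state <- list(weights = rep(1 / 3, 3), series = c(3, 6, 9))
  expect_equal(predict_adaptive_filter(state, 1, "recursive")$forecast, 6)
})

test_that("LMS learns a periodic signal and is a fixed point on constants", {
  x <- rep(c(10, 20, 30), 60)
  fit <- fit_adaptive_filter(x, N = 3)
  pred <- predict_adaptive_filter(fit, 1, "recursive")$forecast
  nxt <- 10  # the cycle continues
  expect_lt(abs(pred - nxt), 0.01 * mean(x))

  const <- fit_adaptive_filter(rep(7, 30), N = 4)
  expect_true(const$converged)
  expect_identical(const$rounds_run, 1L)
  expect_equal(const$weights, rep(0.25, 4))
})

test_that("round MAE does not increase at an admissible k; huge k diverges", {
  descends <- vapply(1:20, function(seed) {
    x <- sim_arma_vec(200, phi = 0.7, seed = 400 + seed)
    fit <- fit_adaptive_filter(x, N = 3, max_rounds = 30)
    utils::tail(fit$trace$mae, 1) <= fit$trace$mae[1] + 1e-9
  }, logical(1))
  expect_true(all(descends))

  x <- sim_arma_vec(200, phi = 0.7, seed = 999)
  expect_error(fit_adaptive_filter(x, N = 3, k = 100 * learning_bound(x)),
               class = "dc_divergence")
})

test_that("weight recovery: LMS converges to a generating weight vector", {
  # noise-free oscillation x_t = 2 cos(2 pi / 7) x_{t-1} - x_{t-2}: the unique
  # zero-error weight pair on this signal is w* = (2 cos(2 pi / 7), -1)
  w_star <- c(2 * cos(2 * pi / 7), -1)
  x <- numeric(2000)
  x[1:2] <- c(1, 0.5)
  for (t in 3:2000) x[t] <- sum(w_star * x[(t - 1):(t - 2)])
  fit <- fit_adaptive_filter(x, N = 2, max_rounds = 2000, tol = 0)
  expect_equal(fit$weights, w_star, tolerance = 1e-3)
})

test_that("iteration accounting matches rounds x (M - N)", {
  x <- sim_arma_vec(100, phi = 0.5, seed = 5)
  fit <- fit_adaptive_filter(x, N = 4, max_rounds = 7, tol = 0)
  expect_identical(fit$total_iterations, fit$rounds_run * (100L - 4L))
  expect_identical(length(fit$per_step_errors), 96L)
})
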