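#' Regressor vector of the ARMA one-step predictor
#'
#' Viewing the ARMA equation as a weighted polynomial in past observations
#' and past innovations, the coefficient vector `(phi_1..phi_p,
#' theta_1..theta_q)` multiplies the regressor
#' `(y_{t-1},..,y_{t-p}, -e_{t-1},..,-e_{t-q})`: the innovation entries carry
#' a negative sign so that the dot product plus `phi0` reproduces the model's
#' one-step prediction exactly, and so that the LMS update on this vector is
#' the true steepest-descent step for the model's parameterization.
#'
#' @param history Differenced-scale observations `y` (numeric vector).
#' @param residuals Innovation sequence aligned with `history`.
#' @param t Target index (`> max(p, q)`): the vector predicts `y_t`.
#' @param p,q AR and MA orders.
#'
#' @return Numeric vector of length `p + q`.
#' @examples
#' regressor_vector(c(2, 4), c(0.5, 1), t = 3, p = 1, q = 1) # c(4, -1)
#' @export
regressor_vector <- function(history, residuals, t, p, q) {
  p <- check_count(p, "p"); q <- check_count(q, "q")
  t <- check_count(t, "t")
  if (t <= max(p, q) || t > length(history) + 1L) {
    abort("`t` must exceed max(p, q) and lie within the history.",
          class = "dc_invalid_argument")
  }
  c(if (p > 0L) history[t - seq_len(p)],
    if (q > 0L) -residuals[t - seq_len(q)])
}

#' Refine ARMA coefficients by self-adaptive filtering
#'
#' Treats the estimated AR/MA coefficients as adaptive-filter weights and
#' adjusts them by per-step steepest-descent updates over the training data.
#' Each round sweeps the differenced training series forward, maintaining
#' the innovation recursion with the current (evolving) weights: every
#' one-step error both updates the weights and is stored as the innovation
#' used by later regressors. The constant `phi0` is frozen by default. Rounds
#' stop when the round mean absolute error converges (relative change
#' `< tol`) or after `max_rounds`; a 10-fold MAE increase over the reference
#' level aborts with a divergence error.
#'
#' @param object `arima_css` fit to refine (estimated on its own series).
#' @param k Learning constant, or `NULL` for the [learning_bound()] computed
#'   on the scale selected by `k_scale`.
#' @param k_scale Scale of the automatic bound: `"raw"` (default) uses the
#'   undifferenced training observations, `"differenced"` the modelling
#'   scale.
#' @param tol Round-MAE convergence tolerance (default `1e-6`).
#' @param max_rounds Maximum rounds (default 100; 0 disables refinement).
#' @param residual_mode `"evolving"` (default) recomputes innovations with
#'   the current weights during the sweep; `"frozen"` keeps the initial
#'   model's innovation sequence fixed within each round (sensitivity
#'   check).
#' @param refine_constant Also update `phi0`? Default `FALSE`.
#'
#' @return Object of class `hybrid_refit`: list with `before` and `after`
#'   (`arima_css` objects sharing orders), `trace` (tibble `round`, `mae`),
#'   `rounds_run`, `total_iterations`, `converged`, `k`.
#' @export
refine_arima <- function(object, k = NULL, k_scale = c("raw", "differenced"),
                         tol = 1e-6, max_rounds = 100L,
                         residual_mode = c("evolving", "frozen"),
                         refine_constant = FALSE) {
  stopifnot(inherits(object, "arima_css"))
  k_scale <- match.arg(k_scale)
  residual_mode <- match.arg(residual_mode)
  max_rounds <- check_count(max_rounds, "max_rounds")
  p <- object$order[["p"]]; q <- object$order[["q"]]; d <- object$order[["d"]]
  x <- object$series
  y <- if (d > 0L) diff(x, differences = d) else x
  n <- length(y)
  if (is.null(k)) {
    k <- learning_bound(if (k_scale == "raw") x else y)
  }
  if (k < 0) abort("`k` must be non-negative.", class = "dc_invalid_argument")

  w <- c(object$phi, object$theta)
  phi0 <- object$phi0
  s <- max(p, q) + 1L
  if (s > n) abort("Orders exceed the differenced series length.", class = "dc_invalid_argument")
  frozen_eps <- if (residual_mode == "frozen") {
    arma_innovations(y, object$phi0, object$phi, object$theta)
  } else NULL

  maes <- numeric(0)
  converged <- FALSE
  scale0 <- mean(abs(y - mean(y)))
  r <- 0L
  while (r < max_rounds) {
    r <- r + 1L
    eps <- numeric(n)
    abs_sum <- 0
    for (t in s:n) {
      z <- c(if (p > 0L) y[t - seq_len(p)],
             if (q > 0L) -(if (is.null(frozen_eps)) eps else frozen_eps)[t - seq_len(q)])
      e <- y[t] - (phi0 + sum(w * z))
      eps[t] <- e
      abs_sum <- abs_sum + abs(e)
      upd <- lms_update(c(if (refine_constant) phi0, w), k, e,
                        c(if (refine_constant) 1, z))
      if (refine_constant) {
        phi0 <- upd[1L]
        w <- upd[-1L]
      } else {
        w <- upd
      }
    }
    maes <- c(maes, abs_sum / (n - s + 1L))
    ref <- min(maes[1L], if (scale0 > 0) scale0 else maes[1L])
    if (!is.finite(maes[r]) || maes[r] > 10 * ref + 1e-12) {
      abort(sprintf(
        "Refinement diverged (round MAE grew 10-fold); k = %.3g exceeds a stable step, bound = %.3g.",
        k, learning_bound(if (k_scale == "raw") x else y)), class = "dc_divergence")
    }
    if (maes[r] < tol || (r > 1L && abs(maes[r] - maes[r - 1L]) / max(maes[r - 1L], 1e-300) < tol)) {
      converged <- TRUE
      break
    }
  }

  after <- object
  after$phi0 <- phi0
  after$phi <- if (p > 0L) w[seq_len(p)] else numeric(0)
  after$theta <- if (q > 0L) w[p + seq_len(q)] else numeric(0)
  # refreshed diagnostics on the refined coefficients
  e_after <- arma_innovations(y, after$phi0, after$phi, after$theta)
  after$rss <- sum(e_after[(p + 1L):n]^2)
  after$sigma2 <- after$rss / object$n_eff
  after$std_errors <- rep(NA_real_, length(object$std_errors))
  after$t_stats <- rep(NA_real_, length(object$t_stats))
  warn_unit_roots(after$phi, after$theta)

  structure(
    list(
      before = object,
      after = after,
      trace = tibble(round = seq_along(maes), mae = maes),
      rounds_run = length(maes),
      total_iterations = length(maes) * (n - s + 1L),
      converged = converged,
      k = k
    ),
    class = "hybrid_refit"
  )
}

#' @export
print.hybrid_refit <- function(x, ...) {
  cat(sprintf("Coefficient refinement: %d round(s) (%d updates), k = %.3g, %s\n",
              x$rounds_run, x$total_iterations, x$k,
              if (x$converged) "converged" else "stopped at max_rounds"))
  print(tidy(x), ...)
  invisible(x)
}

#' @export
tidy.hybrid_refit <- function(x, ...) {
  b <- tidy(x$before)
  a <- tidy(x$after)
  tibble(term = b$term, before = b$estimate, after = a$estimate)
}

#' @export
glance.hybrid_refit <- function(x, ...) {
  tibble(rounds_run = x$rounds_run, total_iterations = x$total_iterations,
         k = x$k, converged = x$converged,
         mae_first = if (x$rounds_run > 0L) x$trace$mae[1L] else NA_real_,
         mae_last = if (x$rounds_run > 0L) utils::tail(x$trace$mae, 1L) else NA_real_)
}

#' End-to-end hybrid forecasting pipeline
#'
#' Runs the full workflow on a training/verification split: automatic
#' differencing choice (ADF-based), order selection over a criterion grid,
#' conditional-least-squares estimation, steepest-descent coefficient
#' refinement, and rolling one-step forecasts over the verification window
#' with both the plain and the refined model, summarised by paired error
#' metrics.
#'
#' @param train,verify Series tibbles or numeric vectors.
#' @param d Differencing order, or `"auto"` (default) for [choose_d()].
#' @param max_p,max_q Grid bounds for [select_order()]; `NULL` for the
#'   `floor(log(n))` default.
#' @param criterion `"bic"` (default) or `"aic"`.
#' @param include_constant Estimate the constant term? Default `TRUE`.
#' @param k,k_scale,tol,max_rounds,residual_mode Passed to [refine_arima()].
#' @param adf_variant ADF deterministic-term variant for the automatic `d`.
#'
#' @return Object of class `hybrid_forecast`: list with `d`, `grid`
#'   (`order_grid`), `fit`, `refit` (`hybrid_refit`), `forecasts` (tibble
#'   `step`, `actual`, `arima`, `hybrid`), `metrics` (two-row tibble keyed by
#'   `model`), and the stationarity reports.
#' @export
hybrid_pipeline <- function(train, verify, d = "auto", max_p = NULL, max_q = NULL,
                            criterion = c("bic", "aic"), include_constant = TRUE,
                            k = NULL, k_scale = c("raw", "differenced"),
                            tol = 1e-6, max_rounds = 100L,
                            residual_mode = c("evolving", "frozen"),
                            adf_variant = "none") {
  criterion <- match.arg(criterion)
  k_scale <- match.arg(k_scale)
  residual_mode <- match.arg(residual_mode)
  x_train <- series_values(train, "train")
  x_verify <- series_values(verify, "verify")
  horizon <- length(x_verify)
  if (horizon < 1L) abort("`verify` must contain at least one point.", class = "dc_invalid_argument")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "dc_pipeline_failure", parent = e)
    })
  }

  adf0 <- stage("stationarity", adf_test(x_train, variant = adf_variant))
  lb0 <- stage("stationarity", ljung_box_test(x_train))
  d_used <- if (identical(d, "auto")) {
    as.integer(stage("stationarity", choose_d(x_train, variant = adf_variant)))
  } else {
    check_count(d, "d")
  }
  grid <- stage("identification",
                select_order(x_train, d = d_used, max_p = max_p, max_q = max_q,
                             criterion = criterion, include_constant = include_constant))
  fit <- grid$fit
  refit <- stage("refinement",
                 if (max_rounds == 0L) {
                   structure(list(before = fit, after = fit,
                                  trace = tibble(round = integer(), mae = numeric()),
                                  rounds_run = 0L, total_iterations = 0L,
                                  converged = TRUE,
                                  k = k %||% learning_bound(if (k_scale == "raw") x_train else
                                    if (d_used > 0) diff(x_train, differences = d_used) else x_train)),
                             class = "hybrid_refit")
                 } else {
                   refine_arima(fit, k = k, k_scale = k_scale, tol = tol,
                                max_rounds = max_rounds, residual_mode = residual_mode)
                 })
  fc_plain <- stage("forecast", forecast_arima(fit, horizon, "rolling", x_verify))
  fc_hybrid <- stage("forecast", forecast_arima(refit$after, horizon, "rolling", x_verify))
  forecasts <- tibble(
    step = seq_len(horizon),
    actual = x_verify,
    arima = fc_plain$forecast,
    hybrid = fc_hybrid$forecast
  )
  dates <- series_dates(verify)
  if (!is.null(dates)) forecasts <- dplyr::mutate(forecasts, date = dates, .before = 1L)
  metrics <- dplyr::bind_rows(
    dplyr::mutate(forecast_metrics(x_verify, fc_plain$forecast), model = "arima", .before = 1L),
    dplyr::mutate(forecast_metrics(x_verify, fc_hybrid$forecast), model = "hybrid", .before = 1L)
  )
  structure(
    list(
      d = d_used,
      adf = adf0, ljung_box = lb0,
      grid = grid, fit = fit, refit = refit,
      forecasts = forecasts,
      metrics = metrics
    ),
    class = "hybrid_forecast"
  )
}

#' @export
print.hybrid_forecast <- function(x, ...) {
  cat(sprintf("Hybrid pipeline: d = %d, selected ARIMA(%d, %d, %d), %d refinement round(s)\n",
              x$d, x$grid$selected_p, x$d, x$grid$selected_q, x$refit$rounds_run))
  print(x$metrics, ...)
  invisible(x)
}

#' @export
glance.hybrid_forecast <- function(x, ...) {
  tibble(
    d = x$d, p = x$grid$selected_p, q = x$grid$selected_q,
    k = x$refit$k, rounds_run = x$refit$rounds_run,
    converged = x$refit$converged,
    mape_arima = x$metrics$mape[x$metrics$model == "arima"],
    mape_hybrid = x$metrics$mape[x$metrics$model == "hybrid"]
  )
}

#' @export
tidy.hybrid_forecast <- function(x, ...) x$metrics
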