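#' Sample autocorrelation and partial autocorrelation
#'
#' Thin tidy wrappers around [stats::acf()] and [stats::pacf()]. `acf_series`
#' includes lag 0 (always 1); `pacf_series` starts at lag 1.
#'
#' @param data Series tibble or numeric vector; must not be constant.
#' @param max_lag Largest lag, `max_lag < length(data)`.
#'
#' @return Tibble with columns `lag` and `acf` (or `pacf`).
#' @export
acf_series <- function(data, max_lag = NULL) {
  x <- series_values(data, "data")
  n <- length(x)
  max_lag <- if (is.null(max_lag)) min(n - 1L, 10L * floor(log10(n))) else check_count(max_lag, "max_lag")
  if (max_lag >= n) {
    abort("`max_lag` must be smaller than the series length.", class = "dc_invalid_argument")
  }
  if (sd(x) == 0) {
    abort("Series is constant; autocorrelations are undefined.", class = "dc_undefined_metric")
  }
  a <- acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)
  tibble(lag = 0:max_lag, acf = as.numeric(a$acf))
}

#' @rdname acf_series
#' @export
pacf_series <- function(data, max_lag = NULL) {
  x <- series_values(data, "data")
  n <- length(x)
  max_lag <- if (is.null(max_lag)) min(n - 1L, 10L * floor(log10(n))) else check_count(max_lag, "max_lag")
  if (max_lag >= n) {
    abort("`max_lag` must be smaller than the series length.", class = "dc_invalid_argument")
  }
  if (sd(x) == 0) {
    abort("Series is constant; autocorrelations are undefined.", class = "dc_undefined_metric")
  }
  a <- pacf(x, lag.max = max_lag, plot = FALSE)
  tibble(lag = seq_len(max_lag), pacf = as.numeric(a$acf))
}

#' Penalized information criterion
#'
#' `aic = -2 loglik + 2 m` and `bic = -2 loglik + m log(n)` where `m` is the
#' number of free mean-model parameters.
#'
#' @param loglik Log-likelihood of the fitted model.
#' @param n_params Number of parameters `m` (count of constant, AR and MA
#'   coefficients; the innovation variance is excluded by convention here).
#' @param n_obs Effective number of observations.
#' @param kind `"bic"` (default) or `"aic"`.
#'
#' @return Single numeric criterion value (smaller is better).
#' @export
information_criterion <- function(loglik, n_params, n_obs, kind = c("bic", "aic")) {
  kind <- match.arg(kind)
  if (n_params < 1 || n_obs < n_params) {
    abort("Need `n_obs` >= `n_params` >= 1.", class = "dc_invalid_argument")
  }
  if (kind == "aic") -2 * loglik + 2 * n_params else -2 * loglik + n_params * log(n_obs)
}

# One-step innovations of the ARMA recursion on the (already differenced)
# series y, under the sign convention
#   y_t = phi0 + sum_i phi_i y_{t-i} + e_t - sum_j theta_j e_{t-j}.
# Conditional treatment: the first p observations are conditioned on and get
# residual 0; pre-sample innovations are 0. The MA feedback is a linear
# recursive filter, so it vectorizes through stats::filter.
arma_innovations <- function(y, phi0, phi, theta) {
  n <- length(y)
  p <- length(phi)
  q <- length(theta)
  a <- y - phi0
  if (p > 0L) {
    for (i in seq_len(p)) {
      a[(i + 1L):n] <- a[(i + 1L):n] - phi[i] * y[seq_len(n - i)]
    }
    a[seq_len(p)] <- 0
  }
  eps <- if (q > 0L) as.numeric(stats::filter(a, theta, method = "recursive")) else a
  if (p > 0L) eps[seq_len(p)] <- 0
  eps
}

# Soft barrier keeping estimation inside the stationary/invertible region:
# conditional least squares otherwise rewards spurious solutions with
# near-cancelling root pairs on the unit circle. The barrier is relative to
# the RSS so its strength is scale free; estimates may still end arbitrarily
# close to (but not beyond) the boundary.
root_violation <- function(cf) {
  if (length(cf) == 0L) return(0)
  r <- Mod(polyroot(c(1, -cf)))
  sum(pmax(0, 1 - r))
}

css_objective <- function(par, y, p, q, include_constant, barrier = TRUE) {
  i <- 1L
  phi0 <- 0
  if (include_constant) {
    phi0 <- par[1L]
    i <- 2L
  }
  phi <- if (p > 0L) par[i:(i + p - 1L)] else numeric(0)
  theta <- if (q > 0L) par[(i + p):(i + p + q - 1L)] else numeric(0)
  if ((p && any(abs(phi) > 50)) || (q && any(abs(theta) > 50))) return(1e300)
  e <- arma_innovations(y, phi0, phi, theta)
  rss <- sum(e[(p + 1L):length(y)]^2)
  if (!is.finite(rss)) return(1e300)
  if (barrier) {
    viol <- root_violation(phi) + root_violation(theta)
    if (viol > 0) rss <- rss * (1 + (viol / 0.01)^2)
  }
  rss
}

# Hannan-Rissanen style starting values: a long AR regression supplies proxy
# innovations, then y is regressed on its own lags and lagged proxies.
hr_start <- function(y, p, q) {
  n <- length(y)
  m <- min(max(8L, 2L * (p + q)), floor(n / 4))
  yc <- y - mean(y)
  Z <- embed(yc, m + 1L)
  e_proxy <- tryCatch(stats::lsfit(Z[, -1L, drop = FALSE], Z[, 1L], intercept = FALSE)$residuals,
                      error = function(e) NULL)
  if (is.null(e_proxy)) return(NULL)
  ehat <- c(rep(0, m), e_proxy)
  k <- max(p, q)
  rows <- (k + 1L):n
  X <- NULL
  if (p > 0L) X <- cbind(X, sapply(seq_len(p), function(i) yc[rows - i]))
  if (q > 0L) X <- cbind(X, sapply(seq_len(q), function(j) ehat[rows - j]))
  cf <- tryCatch(stats::lsfit(X, yc[rows], intercept = FALSE)$coefficients,
                 error = function(e) NULL)
  if (is.null(cf) || anyNA(cf)) return(NULL)
  phi <- if (p > 0L) cf[seq_len(p)] else numeric(0)
  # regression estimates the MA part with a plus sign; our convention is minus
  theta <- if (q > 0L) -cf[p + seq_len(q)] else numeric(0)
  phi <- pmin(pmax(phi, -0.95), 0.95)
  theta <- pmin(pmax(theta, -0.95), 0.95)
  list(phi = phi, theta = theta)
}

#' Conditional-least-squares ARMA estimation
#'
#' Differences the series `d` times, then estimates the constant and the AR
#' and MA coefficients of
#' \deqn{y_t = \phi_0 + \phi_1 y_{t-1} + \dots + \phi_p y_{t-p} + \epsilon_t
#'       - \theta_1 \epsilon_{t-1} - \dots - \theta_q \epsilon_{t-q}}
#' by minimizing the conditional sum of squared innovations (pre-sample
#' innovations fixed at zero, first `p` observations conditioned on).
#' `sigma2` is `RSS / n_eff`; standard errors come from the numerical
#' curvature of the objective at the optimum; the Gaussian log-likelihood
#' implied by the RSS is stored for criterion use.
#'
#' Stationarity/invertibility of the estimates is checked and reported as a
#' warning only: refined coefficients are expected to live near the unit
#' circle.
#'
#' @param data Series tibble or numeric vector (observation scale).
#' @param p,d,q Non-negative integer orders.
#' @param include_constant Estimate \eqn{\phi_0}? Default `TRUE`.
#'
#' @return Object of class `arima_css`: a list with `order`, `phi0`, `phi`,
#'   `theta`, `sigma2`, `std_errors`, `t_stats`, `loglik`, `aic`, `bic`,
#'   `rss`, `n`, `n_eff`, `converged`, and the training series.
#' @export
estimate_arima <- function(data, p, d = 0L, q = 0L, include_constant = TRUE) {
  x <- series_values(data, "data")
  p <- check_count(p, "p"); d <- check_count(d, "d"); q <- check_count(q, "q")
  if (length(x) - d <= p + q + 1L + include_constant) {
    abort("Series too short for the requested orders.", class = "dc_insufficient_data")
  }
  if (length(x) - d <= 3L * (p + q + 1L)) {
    warn("Fewer than 3 observations per parameter; estimates will be fragile.")
  }
  y <- if (d > 0L) diff(x, differences = d) else x
  n <- length(y)
  n_par <- include_constant + p + q

  if (n_par == 0L) {
    # pure white-noise model, nothing to optimize
    e <- y
    rss <- sum(e^2)
    return(new_arima_css(x, y, p, d, q, include_constant,
                         phi0 = 0, phi = numeric(0), theta = numeric(0),
                         rss = rss, hessian = NULL, converged = TRUE))
  }

  starts <- list(c(if (include_constant) mean(y) * 0.5 else NULL, rep(0.05, p), rep(0, q)))
  hs <- if (p + q > 0L) hr_start(y, p, q) else NULL
  if (!is.null(hs)) {
    starts <- c(starts, list(c(if (include_constant) mean(y) * (1 - sum(hs$phi)) else NULL,
                               hs$phi, hs$theta)))
  }
  # closure avoids partial matching of objective args against optim's formals
  obj <- function(par) css_objective(par, y, p, q, include_constant)
  best <- NULL
  for (st in starts) {
    o <- tryCatch(
      optim(st, obj, method = "BFGS", control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (!is.null(o) && is.finite(o$value) && o$value < 1e299 &&
        (is.null(best) || o$value < best$value)) {
      best <- o
    }
  }
  if (is.null(best)) {
    abort("CSS optimization failed to produce a finite objective.",
          class = "dc_estimation_failure")
  }
  obj_free <- function(par) css_objective(par, y, p, q, include_constant, barrier = FALSE)
  best$value <- obj_free(best$par)
  H <- tryCatch(stats::optimHess(best$par, obj_free), error = function(e) NULL)
  i <- 1L
  phi0 <- 0
  if (include_constant) { phi0 <- best$par[1L]; i <- 2L }
  phi <- if (p > 0L) best$par[i:(i + p - 1L)] else numeric(0)
  theta <- if (q > 0L) best$par[(i + p):(i + p + q - 1L)] else numeric(0)
  new_arima_css(x, y, p, d, q, include_constant, phi0, phi, theta,
                rss = best$value, hessian = H, converged = best$convergence == 0L)
}

new_arima_css <- function(x, y, p, d, q, include_constant, phi0, phi, theta,
                          rss, hessian, converged) {
  n <- length(y)
  n_eff <- n - p
  sigma2 <- rss / n_eff
  loglik <- -n_eff / 2 * (log(2 * pi * sigma2) + 1)
  m <- include_constant + p + q
  se <- tstat <- rep(NA_real_, m)
  if (!is.null(hessian) && m > 0L) {
    cov <- tryCatch(2 * sigma2 * solve(hessian), error = function(e) NULL)
    if (!is.null(cov)) {
      dg <- diag(cov)
      se <- ifelse(dg > 0, sqrt(dg), NA_real_)
      tstat <- c(phi0[include_constant], phi, theta) / se
    }
  }
  warn_unit_roots(phi, theta)
  structure(
    list(
      order = c(p = p, d = d, q = q),
      phi0 = unname(phi0), phi = unname(phi), theta = unname(theta),
      include_constant = include_constant,
      sigma2 = sigma2, rss = rss,
      std_errors = unname(se), t_stats = unname(tstat),
      loglik = loglik,
      aic = if (m > 0) information_criterion(loglik, m, n_eff, "aic") else -2 * loglik,
      bic = if (m > 0) information_criterion(loglik, m, n_eff, "bic") else -2 * loglik,
      n = length(x), n_eff = n_eff,
      series = x,
      converged = converged
    ),
    class = "arima_css"
  )
}

warn_unit_roots <- function(phi, theta, tol = 1.01) {
  near <- function(cf) {
    if (length(cf) == 0L) return(FALSE)
    r <- tryCatch(Mod(polyroot(c(1, -cf))), error = function(e) numeric(0))
    length(r) > 0 && any(r <= tol)
  }
  if (near(phi)) warn("AR roots on or near the unit circle; model is close to non-stationary.")
  if (near(theta)) warn("MA roots on or near the unit circle; model is close to non-invertible.")
  invisible(NULL)
}

#' Model innovations (one-step training residuals)
#'
#' Runs the conditional innovation recursion of a fitted or hand-built model
#' over a series on its differenced scale: `e_t = y_t - phi0 - sum(phi_i
#' y_{t-i}) + sum(theta_j e_{t-j})`, with pre-sample innovations 0 and the
#' first `p` observations conditioned on (residual 0). These equal the
#' model's rolling one-step training errors by construction.
#'
#' @param object An `arima_css` fit (its own training series is used unless
#'   `data` is supplied).
#' @param data Optional series tibble or numeric vector (observation scale).
#'
#' @return Tibble with columns `fitted` and `residual`, aligned to the
#'   differenced index.
#' @export
model_residuals <- function(object, data = NULL) {
  stopifnot(inherits(object, "arima_css"))
  x <- if (is.null(data)) object$series else series_values(data, "data")
  d <- object$order[["d"]]
  y <- if (d > 0L) diff(x, differences = d) else x
  e <- arma_innovations(y, object$phi0, object$phi, object$theta)
  tibble(fitted = y - e, residual = e)
}

#' @export
residuals.arima_css <- function(object, ...) model_residuals(object)$residual

#' Order selection over a (p, q) grid by information criterion
#'
#' Fits every `(p, q)` combination with `p <= max_p`, `q <= max_q` (the
#' `(0, 0)` cell is a mean-only model) by conditional least squares on the
#' `d`-times differenced series and tabulates the criterion. Failed fits are
#' recorded as `Inf`. The selected order is the finite minimum; exact ties
#' break toward smaller `p + q`, then smaller `p`.
#'
#' @param data Series tibble or numeric vector.
#' @param d Differencing order applied before fitting.
#' @param max_p,max_q Grid bounds; default `floor(log(n))` (rows index `p`
#'   from 0, columns `q` from 0, matching the conventional BIC-matrix layout).
#' @param criterion `"bic"` (default) or `"aic"`.
#' @param include_constant Passed to [estimate_arima()].
#'
#' @return Object of class `order_grid`: list with `criterion_matrix`,
#'   `selected_p`, `selected_q`, `criterion`, and the winning `fit`.
#' @export
select_order <- function(data, d = 0L, max_p = NULL, max_q = NULL,
                         criterion = c("bic", "aic"), include_constant = TRUE) {
  x <- series_values(data, "data")
  criterion <- match.arg(criterion)
  d <- check_count(d, "d")
  n <- length(x) - d
  if (is.null(max_p)) max_p <- max(1L, floor(log(n)))
  if (is.null(max_q)) max_q <- max(1L, floor(log(n)))
  max_p <- check_count(max_p, "max_p"); max_q <- check_count(max_q, "max_q")

  cells <- order_cells(max_p, max_q)
  fits <- purrr::map(seq_len(nrow(cells)), function(i) {
    # exploratory cells legitimately hit boundaries; their warnings are noise
    tryCatch(
      suppressWarnings(
        estimate_arima(x, p = cells$p[i], d = d, q = cells$q[i],
                       include_constant = include_constant)
      ),
      error = function(e) NULL
    )
  })
  # criterion evaluated over the common window t > max_p so that every cell
  # is judged on the same predicted observations (comparable likelihoods)
  y <- if (d > 0L) diff(x, differences = d) else x
  n_common <- length(y) - max_p
  vals <- purrr::map2_dbl(fits, seq_len(nrow(cells)), function(f, i) {
    if (is.null(f)) return(Inf)
    e <- arma_innovations(y, f$phi0, f$phi, f$theta)
    rss <- sum(e[(max_p + 1L):length(y)]^2)
    ll <- -n_common / 2 * (log(2 * pi * rss / n_common) + 1)
    m <- include_constant + cells$p[i] + cells$q[i]
    if (m == 0L) return(-2 * ll)
    information_criterion(ll, m, n_common, criterion)
  })
  if (all(!is.finite(vals))) {
    abort("Every (p, q) fit failed; cannot identify an order.",
          class = "dc_identification_failure")
  }
  # ties: smallest criterion, then smallest p + q, then smallest p
  ord <- order(vals, cells$p + cells$q, cells$p)
  win <- ord[1L]
  mat <- matrix(vals, nrow = max_p + 1L, ncol = max_q + 1L, byrow = TRUE,
                dimnames = list(p = 0:max_p, q = 0:max_q))
  structure(
    list(
      criterion_matrix = mat,
      selected_p = cells$p[win],
      selected_q = cells$q[win],
      criterion = criterion,
      fit = fits[[win]],
      d = d
    ),
    class = "order_grid"
  )
}

order_cells <- function(max_p, max_q) {
  # row-major (p outer) so the matrix fill above lines up
  tibble(
    p = rep(0:max_p, each = max_q + 1L),
    q = rep(0:max_q, times = max_p + 1L)
  )
}

#' Forecast from a fitted ARMA model
#'
#' One-step predictions on the differenced scale,
#' `yhat_t = phi0 + sum(phi_i y_{t-i}) - sum(theta_j e_{t-j})`, integrated
#' back to the observation scale. In `"rolling"` mode the true observation
#' (and its implied innovation) is absorbed after each step, mirroring
#' rolling one-step-ahead evaluation; in `"recursive"` mode predictions are
#' fed back with future innovations set to zero.
#'
#' @param object `arima_css` fit (forecasts continue its training series).
#' @param horizon Number of steps ahead.
#' @param mode `"rolling"` (requires `actuals`) or `"recursive"`.
#' @param actuals Numeric vector or series tibble of length `horizon` with
#'   the observations to absorb in rolling mode.
#'
#' @return Tibble with columns `step`, `forecast` and, in rolling mode,
#'   `actual`.
#' @export
forecast_arima <- function(object, horizon, mode = c("rolling", "recursive"),
                           actuals = NULL) {
  stopifnot(inherits(object, "arima_css"))
  mode <- match.arg(mode)
  horizon <- check_count(horizon, "horizon")
  if (mode == "rolling") {
    if (is.null(actuals)) {
      abort("Rolling mode needs `actuals` of length `horizon`.", class = "dc_invalid_argument")
    }
    actuals <- series_values(actuals, "actuals")
    if (length(actuals) != horizon) {
      abort("`actuals` must have length `horizon`.", class = "dc_invalid_argument")
    }
  }
  path <- arma_forecast_path(object$series, object$order[["d"]], object$phi0,
                             object$phi, object$theta, horizon, mode, actuals)
  if (mode == "rolling") {
    tibble(step = seq_len(horizon), forecast = path, actual = actuals)
  } else {
    tibble(step = seq_len(horizon), forecast = path)
  }
}

# Shared forecasting engine. Maintains the differenced-scale history and the
# innovation sequence (continuing the conditional recursion used in
# estimation), integrating each one-step prediction to the observation scale.
arma_forecast_path <- function(x, d, phi0, phi, theta, horizon, mode, actuals) {
  p <- length(phi); q <- length(theta)
  y <- if (d > 0L) diff(x, differences = d) else x
  eps <- arma_innovations(y, phi0, phi, theta)
  obs <- x
  out <- numeric(horizon)
  for (h in seq_len(horizon)) {
    t_next <- length(y) + 1L
    ar <- if (p) sum(phi * y[t_next - seq_len(p)]) else 0
    ma <- if (q) sum(theta * eps[t_next - seq_len(q)]) else 0
    yhat <- phi0 + ar - ma
    xhat <- if (d > 0L) {
      utils::tail(diffinv(yhat, differences = d, xi = utils::tail(obs, d)), 1L)
    } else {
      yhat
    }
    out[h] <- xhat
    if (mode == "rolling") {
      a <- actuals[h]
      y_new <- if (d > 0L) {
        diff(c(utils::tail(obs, d), a), differences = d)
      } else {
        a
      }
      eps <- c(eps, y_new - yhat)
      y <- c(y, y_new)
      obs <- c(obs, a)
    } else {
      eps <- c(eps, 0)
      y <- c(y, if (d > 0L) diff(c(utils::tail(obs, d), xhat), differences = d) else yhat)
      obs <- c(obs, xhat)
    }
  }
  out
}

#' @export
print.arima_css <- function(x, ...) {
  o <- x$order
  cat(sprintf("ARIMA(%d, %d, %d) fitted by conditional least squares\n",
              o[["p"]], o[["d"]], o[["q"]]))
  print(tidy(x), ...)
  cat(sprintf("sigma^2 = %.4g, BIC = %.4f, n = %d (n_eff = %d)\n",
              x$sigma2, x$bic, x$n, x$n_eff))
  invisible(x)
}

#' @export
tidy.arima_css <- function(x, ...) {
  terms <- c(if (x$include_constant) "constant",
             if (length(x$phi)) paste0("ar", seq_along(x$phi)),
             if (length(x$theta)) paste0("ma", seq_along(x$theta)))
  est <- c(if (x$include_constant) x$phi0, x$phi, x$theta)
  if (length(terms) == 0L) {
    return(tibble(term = character(), estimate = numeric(),
                  std.error = numeric(), statistic = numeric()))
  }
  tibble(term = terms, estimate = est,
         std.error = x$std_errors, statistic = x$t_stats)
}

#' @export
glance.arima_css <- function(x, ...) {
  tibble(p = x$order[["p"]], d = x$order[["d"]], q = x$order[["q"]],
         sigma2 = x$sigma2, logLik = x$loglik, AIC = x$aic, BIC = x$bic,
         n = x$n, n_eff = x$n_eff, converged = x$converged)
}

#' @export
print.order_grid <- function(x, ...) {
  cat(sprintf("Order selection by %s over a %dx%d grid; selected (p, q) = (%d, %d)\n",
              toupper(x$criterion), nrow(x$criterion_matrix), ncol(x$criterion_matrix),
              x$selected_p, x$selected_q))
  print(round(x$criterion_matrix, 2))
  invisible(x)
}

#' @export
tidy.order_grid <- function(x, ...) {
  m <- x$criterion_matrix
  out <- tibble(
    p = rep(as.integer(rownames(m)), times = ncol(m)),
    q = rep(as.integer(colnames(m)), each = nrow(m)),
    criterion = as.numeric(m)
  )
  out$selected <- out$p == x$selected_p & out$q == x$selected_q
  out
}

#' Serialize a fitted model to a JSON-ready list
#'
#' @param object `arima_css` fit.
#' @return Named list of orders, coefficients, variance and diagnostics.
#' @export
arima_spec_list <- function(object) {
  stopifnot(inherits(object, "arima_css"))
  list(
    p = unname(object$order[["p"]]), d = unname(object$order[["d"]]),
    q = unname(object$order[["q"]]),
    phi0 = object$phi0, phi = object$phi, theta = object$theta,
    include_constant = object$include_constant,
    sigma2 = object$sigma2, std_errors = object$std_errors,
    t_stats = object$t_stats, loglik = object$loglik,
    aic = object$aic, bic = object$bic, n = object$n, n_eff = object$n_eff,
    converged = object$converged
  )
}
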