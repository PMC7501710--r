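#' Initial adaptive-filter weights
#'
#' All weights start at `1/N`, so the initial filter is the simple moving
#' average of the last `N` observations.
#'
#' @param N Window length (positive integer).
#' @return Numeric vector of `N` equal weights.
#' @export
init_weights <- function(N) {
  N <- check_count(N, "N")
  if (N < 1L) abort("`N` must be at least 1.", class = "dc_invalid_argument")
  rep(1 / N, N)
}

#' Learning-constant stability bound
#'
#' The steepest-descent weight update converges only for a sufficiently small
#' learning constant; the sufficient bound used here is the reciprocal of the
#' largest sum of squared observations over the configured window. In
#' `"full_series"` mode (default) that is the single sum over all training
#' observations; in `"sliding"` mode it is the maximum over all length-`N`
#' windows.
#'
#' @param data Series tibble or numeric vector; must not be all zero.
#' @param window `"full_series"` or `"sliding"`.
#' @param N Window length, required for `"sliding"`.
#'
#' @return Positive scalar bound on `k`.
#' @examples
#' learning_bound(c(3, 4)) # 1 / 25
#' @export
learning_bound <- function(data, window = c("full_series", "sliding"), N = NULL) {
  x <- series_values(data, "data")
  window <- match.arg(window)
  if (all(x == 0)) {
    abort("Series is identically zero; the learning bound is undefined.",
          class = "dc_invalid_argument")
  }
  if (window == "full_series") {
    1 / sum(x^2)
  } else {
    if (is.null(N)) abort("`N` is required for sliding windows.", class = "dc_invalid_argument")
    N <- check_count(N, "N")
    if (N > length(x)) abort("`N` exceeds the series length.", class = "dc_invalid_argument")
    sq <- x^2
    sums <- stats::filter(sq, rep(1, N), sides = 1)
    1 / max(sums, na.rm = TRUE)
  }
}

#' One steepest-descent (LMS) weight update
#'
#' `w_i' = w_i + 2 k e window_i`: the exact negative gradient step of the
#' squared one-step error with respect to the weights, scaled by the learning
#' constant `k`. `window` must be ordered most-recent-first so that `w_1`
#' multiplies the latest observation.
#'
#' @param weights Current weight vector.
#' @param k Learning constant.
#' @param error One-step prediction error `e = x - xhat`.
#' @param window Observations the prediction used, most recent first; same
#'   length as `weights`.
#'
#' @return Updated weight vector.
#' @examples
#' lms_update(c(0.5, 0.5), k = 0.01, error = 2, window = c(1, 2)) # 0.54 0.58
#' @export
lms_update <- function(weights, k, error, window) {
  if (length(weights) != length(window)) {
    abort("`weights` and `window` must have the same length.", class = "dc_invalid_argument")
  }
  weights + 2 * k * error * window
}

#' Fit adaptive-filter weights by repeated LMS sweeps
#'
#' Starting from the equal-weight moving average, sweeps forward through the
#' training series: at each position the filter predicts the next value from
#' the last `N` observations, the prediction error feeds the steepest-descent
#' update, and one round comprises the `M - N` updates of a full pass. The
#' final weights of a round seed the next round; rounds stop when the round
#' mean absolute error (MAE) converges (relative change `< tol`, or absolute
#' MAE `< tol`) or after `max_rounds`. A round MAE exceeding 10 times the
#' first round's MAE aborts with a divergence error naming the admissible
#' learning bound.
#'
#' @param data Training series (tibble or numeric), length `> N`.
#' @param N Window length; default picks the dominant cycle length from the
#'   sample ACF (first significant local maximum at lag >= 2), falling back to
#'   the lag of the largest significant autocorrelation, then to 3.
#' @param k Learning constant; default the `"full_series"` [learning_bound()].
#' @param tol Convergence tolerance on the round MAE (default `1e-6`).
#' @param max_rounds Maximum number of rounds (default 100).
#'
#' @return Object of class `adaptive_filter`: list with `weights`, `N`, `k`,
#'   `trace` (tibble of `round`, `mae`), `per_step_errors` (final round),
#'   `rounds_run`, `total_iterations`, `converged`, and the training series.
#' @export
fit_adaptive_filter <- function(data, N = NULL, k = NULL, tol = 1e-6, max_rounds = 100L) {
  x <- series_values(data, "data")
  M <- length(x)
  if (is.null(N)) N <- default_window_length(x)
  N <- check_count(N, "N")
  if (M <= N) abort("Series must be longer than `N`.", class = "dc_insufficient_data")
  if (is.null(k)) k <- learning_bound(x)
  if (k < 0) abort("`k` must be non-negative.", class = "dc_invalid_argument")
  max_rounds <- check_count(max_rounds, "max_rounds")

  w <- init_weights(N)
  maes <- numeric(0)
  errors <- numeric(0)
  converged <- FALSE
  # divergence reference: round-1 MAE, capped by the series' own absolute
  # deviation so that a round-1 blow-up is itself caught
  scale0 <- mean(abs(x - mean(x)))
  for (r in seq_len(max_rounds)) {
    errors <- numeric(M - N)
    for (t in N:(M - 1L)) {
      win <- x[t:(t - N + 1L)]              # most recent first
      e <- x[t + 1L] - sum(w * win)
      errors[t - N + 1L] <- e
      w <- lms_update(w, k, e, win)
    }
    maes <- c(maes, mean(abs(errors)))
    r_now <- length(maes)
    ref <- min(maes[1L], if (scale0 > 0) scale0 else maes[1L])
    if (!is.finite(maes[r_now]) || maes[r_now] > 10 * ref + 1e-12) {
      abort(sprintf(
        "LMS weight search diverged (round MAE grew 10-fold); k = %.3g exceeds a stable step, bound = %.3g.",
        k, learning_bound(x)), class = "dc_divergence")
    }
    if (maes[r_now] < tol ||
        (r_now > 1L && abs(maes[r_now] - maes[r_now - 1L]) / max(maes[r_now - 1L], 1e-300) < tol)) {
      converged <- TRUE
      break
    }
  }
  rounds <- length(maes)
  structure(
    list(
      weights = w, N = N, k = k,
      trace = tibble(round = seq_len(rounds), mae = maes),
      per_step_errors = errors,
      rounds_run = rounds,
      total_iterations = rounds * (M - N),
      converged = converged,
      series = x
    ),
    class = "adaptive_filter"
  )
}

# Window length heuristic: a cyclic series shows a local ACF maximum at its
# period; otherwise fall back to the strongest significant lag.
default_window_length <- function(x) {
  n <- length(x)
  max_lag <- min(n - 1L, max(10L, floor(n / 4)))
  if (sd(x) == 0) return(3L)
  rho <- as.numeric(acf(x, lag.max = max_lag, plot = FALSE)$acf)[-1L]
  sig <- 2 / sqrt(n)
  if (length(rho) >= 3L) {
    peaks <- which(diff(sign(diff(rho))) == -2) + 1L  # local maxima
    peaks <- peaks[peaks >= 2L & rho[peaks] > sig]
    if (length(peaks) > 0L) return(as.integer(peaks[1L]))
  }
  strongest <- which.max(abs(rho))
  if (abs(rho[strongest]) > sig) return(as.integer(strongest))
  3L
}

#' Forecast with a fitted adaptive filter
#'
#' Applies the weighted-average predictor forward. `"rolling"` mode absorbs
#' the true observation after each step; `"recursive"` mode feeds predictions
#' back.
#'
#' @param object `adaptive_filter` fit (forecasts continue its training
#'   series), or a list with elements `weights` and `series`.
#' @param horizon Steps ahead.
#' @param mode `"rolling"` (requires `actuals`) or `"recursive"`.
#' @param actuals Observations to absorb in rolling mode, length `horizon`.
#'
#' @return Tibble with `step`, `forecast` and, in rolling mode, `actual`.
#' @export
predict_adaptive_filter <- function(object, horizon, mode = c("rolling", "recursive"),
                                    actuals = NULL) {
  mode <- match.arg(mode)
  horizon <- check_count(horizon, "horizon")
  w <- object$weights
  x <- series_values(object$series, "object$series")
  N <- length(w)
  if (length(x) < N) abort("History shorter than the weight window.", class = "dc_invalid_argument")
  if (mode == "rolling") {
    if (is.null(actuals)) {
      abort("Rolling mode needs `actuals` of length `horizon`.", class = "dc_invalid_argument")
    }
    actuals <- series_values(actuals, "actuals")
    if (length(actuals) != horizon) {
      abort("`actuals` must have length `horizon`.", class = "dc_invalid_argument")
    }
  }
  out <- numeric(horizon)
  for (h in seq_len(horizon)) {
    win <- x[length(x):(length(x) - N + 1L)]
    out[h] <- sum(w * win)
    x <- c(x, if (mode == "rolling") actuals[h] else out[h])
  }
  if (mode == "rolling") {
    tibble(step = seq_len(horizon), forecast = out, actual = actuals)
  } else {
    tibble(step = seq_len(horizon), forecast = out)
  }
}

#' @export
print.adaptive_filter <- function(x, ...) {
  cat(sprintf("Adaptive filter: N = %d, k = %.3g, %d round(s), %s\n",
              x$N, x$k, x$rounds_run,
              if (x$converged) "converged" else "stopped at max_rounds"))
  cat("weights:", paste(sprintf("%.4f", x$weights), collapse = " "), "\n")
  invisible(x)
}

#' @export
tidy.adaptive_filter <- function(x, ...) {
  tibble(term = paste0("w", seq_along(x$weights)), estimate = x$weights)
}

#' @export
glance.adaptive_filter <- function(x, ...) {
  tibble(N = x$N, k = x$k, rounds_run = x$rounds_run,
         total_iterations = x$total_iterations,
         mae_first = x$trace$mae[1L], mae_last = utils::tail(x$trace$mae, 1L),
         converged = x$converged)
}
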