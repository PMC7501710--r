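#' Simulate an ARIMA process
#'
#' Generates a seeded realization of
#' `y_t = phi0 + sum(phi_i y_{t-i}) + e_t - sum(theta_j e_{t-j})` driven by
#' Gaussian innovations, followed by `d`-fold cumulative summation. A burn-in
#' of `10 * (p + q + 1)` samples is discarded so recovery tests start from
#' the stationary regime. Identical seeds give identical series.
#'
#' @param n Series length after burn-in.
#' @param phi,theta AR and MA coefficient vectors (may be empty). The MA
#'   coefficients enter with a minus sign, matching the estimation
#'   convention.
#' @param d Integration order (cumulative summation applied after the
#'   stationary recursion).
#' @param phi0 Constant term.
#' @param sigma Innovation standard deviation (`0` gives the deterministic
#'   recursion).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param init Optional starting values for the recursion (length `>= p`,
#'   most recent last). When supplied, burn-in is skipped and the recursion
#'   starts deterministically from these values.
#' @param check_stationary Refuse explosive AR polynomials? Default `TRUE`.
#'
#' @return Tibble with column `value` of length `n`.
#' @examples
#' simulate_arma(5, phi = 0.5, sigma = 0, init = 8) # 8 4 2 1 0.5 decays
#' @export
simulate_arma <- function(n, phi = numeric(0), theta = numeric(0), d = 0L,
                          phi0 = 0, sigma = 1, seed = NULL, init = NULL,
                          check_stationary = TRUE) {
  n <- check_count(n, "n")
  d <- check_count(d, "d")
  p <- length(phi); q <- length(theta)
  if (check_stationary && p > 0L) {
    roots <- Mod(polyroot(c(1, -phi)))
    if (any(roots <= 1)) {
      abort("AR polynomial has roots on or inside the unit circle; pass `check_stationary = FALSE` to override.",
            class = "dc_invalid_argument")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) {
    burn <- 10L * (p + q + 1L)
    total <- n + burn
    e <- rnorm(total, 0, sigma)
    x <- numeric(total)
    for (t in seq_len(total)) {
      ar <- 0
      if (p > 0L) for (i in seq_len(p)) if (t > i) ar <- ar + phi[i] * x[t - i]
      ma <- 0
      if (q > 0L) for (j in seq_len(q)) if (t > j) ma <- ma - theta[j] * e[t - j]
      x[t] <- phi0 + ar + e[t] + ma
    }
    x <- x[(burn + 1L):total]
  } else {
    init <- as.numeric(init)
    if (p > 0L && length(init) < p) {
      abort("`init` must supply at least p starting values.", class = "dc_invalid_argument")
    }
    pre <- length(init)
    total <- n + pre
    e <- c(rep(0, pre), rnorm(n, 0, sigma))
    x <- c(init, numeric(n))
    for (t in (pre + 1L):total) {
      ar <- 0
      if (p > 0L) for (i in seq_len(p)) ar <- ar + phi[i] * x[t - i]
      ma <- 0
      if (q > 0L) for (j in seq_len(q)) if (t > j) ma <- ma - theta[j] * e[t - j]
      x[t] <- phi0 + ar + e[t] + ma
    }
    # the initial values count as the first observations of the recursion
    x <- x[seq_len(n)]
  }
  if (d > 0L) x <- diffinv(x, differences = d)[-seq_len(d)]
  tibble(value = x)
}

#' Simulate a daily outpatient-visit series
#'
#' Deterministic seasonal-mean generator emulating the structure of daily
#' hospital outpatient volumes: a base level with optional linear trend, a
#' multiplicative day-of-week profile (day 1 of the series is a Monday by
#' default), multiplicative holiday dips, and additive Gaussian noise, floored
#' at zero. Defaults portray a mid-size clinic: about 180 visits on an
#' average weekday, a pronounced Monday peak, deep weekend dips, and two
#' golden-week closures (factor 0.25) in the position of the Spring Festival
#' and National Day holidays.
#'
#' @param n_days Number of consecutive calendar days.
#' @param base_level Mean weekday-scale level (visits/day).
#' @param weekly_profile Seven multiplicative factors, Monday first.
#' @param trend_slope Additive change in level per day.
#' @param noise_sd Standard deviation of the additive noise (visits/day).
#' @param holiday_indices 1-based day indices receiving the holiday factor.
#' @param holiday_factor Multiplicative dip in `[0, 1)` applied on holidays.
#' @param seed Integer seed, or `NULL`.
#' @param start_date Date of day 1 (default a Monday, 2017-01-02).
#' @param round_counts Round to whole visits? Default `FALSE`.
#'
#' @return Tibble with columns `date` and `value`.
#' @export
simulate_outpatient <- function(n_days = 441L,
                                base_level = 180,
                                weekly_profile = c(1.25, 1.10, 1.00, 0.95, 1.05, 0.35, 0.25),
                                trend_slope = 0,
                                noise_sd = 15,
                                holiday_indices = c(29:35, 275:281),
                                holiday_factor = 0.25,
                                seed = NULL,
                                start_date = as.Date("2017-01-02"),
                                round_counts = FALSE) {
  n_days <- check_count(n_days, "n_days")
  if (base_level <= 0) abort("`base_level` must be positive.", class = "dc_invalid_argument")
  if (length(weekly_profile) != 7L || any(weekly_profile <= 0)) {
    abort("`weekly_profile` must be 7 positive factors (Monday first).",
          class = "dc_invalid_argument")
  }
  if (holiday_factor < 0 || holiday_factor >= 1) {
    abort("`holiday_factor` must lie in [0, 1).", class = "dc_invalid_argument")
  }
  if (!is.null(seed)) set.seed(seed)
  day <- seq_len(n_days)
  mu <- (base_level + trend_slope * (day - 1L)) * weekly_profile[((day - 1L) %% 7L) + 1L]
  on_holiday <- day %in% holiday_indices
  mu[on_holiday] <- mu[on_holiday] * holiday_factor
  value <- pmax(0, mu + rnorm(n_days, 0, noise_sd))
  if (round_counts) value <- round(value)
  tibble(date = start_date + day - 1L, value = value)
}

#' Drop weekend observations
#'
#' Removes Saturdays and Sundays from a dated series, preserving order; a
#' weekly (period-7) cycle in the input becomes a period-5 cycle in the
#' output.
#'
#' @param data Tibble with `date` and `value` columns.
#' @return Tibble of the weekday rows.
#' @export
remove_weekends <- function(data) {
  dates <- series_dates(data)
  if (is.null(dates)) {
    abort("`data` must have a `date` column to identify weekends.",
          class = "dc_invalid_argument")
  }
  dow <- as.integer(format(dates, "%u"))  # 1 = Monday .. 7 = Sunday
  dplyr::filter(data, dow <= 5L)
}
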