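# Shared fixtures, generated in code at test time.

# numeric vector from the ARMA generator
sim_arma_vec <- function(...) simulate_arma(...)$value

# weekday outpatient fixture in the study shape: simulate daily visits,
# drop weekends, drop the first week, keep 305 weekday points and split
# them 283 training / 22 verification
weekday_split <- function(seed, ...) {
  daily <- simulate_outpatient(n_days = 441L, seed = seed, ...)
  wk <- remove_weekends(daily)
  wk <- wk[-(1:5), ]
  wk <- wk[1:305, ]
  split_series(wk, train_size = 283L)
}

# hand-built ARMA model object for forecasting tests (no estimation)
manual_arima <- function(series, phi0 = 0, phi = numeric(0), theta = numeric(0), d = 0L) {
  p <- length(phi); q <- length(theta)
  y <- if (d > 0) diff(series, differences = d) else series
  structure(
    list(order = c(p = p, d = d, q = q), phi0 = phi0, phi = phi, theta = theta,
         include_constant = phi0 != 0, sigma2 = 1, rss = NA_real_,
         std_errors = rep(NA_real_, p + q), t_stats = rep(NA_real_, p + q),
         loglik = NA_real_, aic = NA_real_, bic = NA_real_,
         n = length(series), n_eff = length(y) - p,
         series = series, converged = TRUE),
    class = "arima_css"
  )
}

seq_len0 <- function(d) if (d == 0L) integer(0) else seq_len(d)
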