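# MacKinnon (2010) response-surface coefficients for Dickey-Fuller critical
# values: cv(level, variant, T) = b0 + b1/T + b2/T^2.
.df_surface <- list(
  none = list(
    `0.01` = c(-2.5658, -1.960, -10.04),
    `0.05` = c(-1.9393, -0.398, 0),
    `0.10` = c(-1.6156, -0.181, 0)
  ),
  constant = list(
    `0.01` = c(-3.4336, -5.999, -29.25),
    `0.05` = c(-2.8621, -2.738, -8.36),
    `0.10` = c(-2.5671, -1.438, -4.48)
  ),
  trend = list(
    `0.01` = c(-3.9638, -8.353, -47.44),
    `0.05` = c(-3.4126, -4.039, -17.83),
    `0.10` = c(-3.1279, -2.418, -7.58)
  )
)

df_critical_value <- function(variant, level, t_eff) {
  tab <- .df_surface[[variant]]
  key <- sprintf("%.2f", level)
  if (!key %in% names(tab)) {
    abort("`level` must be one of 0.01, 0.05, 0.10.", class = "dc_invalid_argument")
  }
  b <- tab[[key]]
  b[1] + b[2] / t_eff + b[3] / t_eff^2
}

#' Augmented Dickey-Fuller unit-root test
#'
#' Regresses the first difference of the series on its lagged level and
#' `lags` lagged differences (plus, optionally, a constant and a linear
#' trend) and reports the t-ratio of the lagged-level coefficient. Rejection
#' of the unit-root null (`reject_null = TRUE`, statistic below the
#' Dickey-Fuller critical value) supports stationarity of the series.
#'
#' Critical values come from response-surface approximations to the
#' Dickey-Fuller distribution; p-values are linear interpolations over the
#' tabulated 1/5/10 percent quantiles, clamped outside that range, and should
#' be read as approximate. Decisions are driven by the critical value.
#'
#' @param data Series tibble or numeric vector, length at least `lags + 10`.
#' @param lags Number of lagged differences in the regression; default
#'   `floor(log(n))`.
#' @param variant Deterministic terms: `"none"` (default), `"constant"`, or
#'   `"trend"` (constant plus linear trend).
#' @param level Test level, one of 0.01, 0.05 (default), 0.10.
#'
#' @return One-row tibble: `statistic`, `critical_value`, `p_value`,
#'   `reject_null`, `lags_used`, `level`, `variant`, `n`.
#' @export
adf_test <- function(data, lags = NULL, variant = c("none", "constant", "trend"),
                     level = 0.05) {
  x <- series_values(data, "data")
  variant <- match.arg(variant)
  n <- length(x)
  lags <- if (is.null(lags)) max(0L, floor(log(n))) else check_count(lags, "lags")
  if (n < lags + 10L) {
    abort("Series too short for the requested ADF lag order.",
          class = "dc_insufficient_data")
  }
  dx <- diff(x)
  # regression rows correspond to level index t = lags+1 .. n-1
  idx <- (lags + 1L):(n - 1L)
  dat <- data.frame(y = dx[idx], level = x[idx])
  for (j in seq_len(lags)) dat[[paste0("dlag", j)]] <- dx[idx - j]
  t_eff <- nrow(dat)
  rhs <- paste(c("level", if (lags > 0L) paste0("dlag", seq_len(lags))), collapse = " + ")
  fml <- switch(variant,
    none = stats::as.formula(paste("y ~ 0 +", rhs)),
    constant = stats::as.formula(paste("y ~", rhs)),
    trend = {
      dat$trend <- seq_len(t_eff)
      stats::as.formula(paste("y ~", rhs, "+ trend"))
    }
  )
  fit <- lm(fml, data = dat)
  stat <- summary(fit)$coefficients["level", "t value"]
  cv <- df_critical_value(variant, level, t_eff)
  cvs <- vapply(c(0.01, 0.05, 0.10), df_critical_value,
                numeric(1), variant = variant, t_eff = t_eff)
  p_value <- stats::approx(cvs, c(0.01, 0.05, 0.10), xout = stat, rule = 2)$y
  out <- tibble(
    statistic = unname(stat),
    critical_value = cv,
    p_value = p_value,
    reject_null = unname(stat) < cv,
    lags_used = lags,
    level = level,
    variant = variant,
    n = n
  )
  attr(out, "p_approx") <- TRUE
  out
}

#' Ljung-Box white-noise test
#'
#' Portmanteau test of the null that the series is white noise, based on
#' `Q = n (n + 2) * sum(acf_h^2 / (n - h))` over lags `1..lags`, referred to a
#' chi-square distribution with `lags` degrees of freedom (computed via
#' [stats::Box.test()]). `reject_null = TRUE` means the series shows
#' autocorrelation, i.e. is *not* white noise.
#'
#' @param data Series tibble or numeric vector; must not be constant.
#' @param lags Number of autocorrelation lags; default `floor(log(n))`.
#' @param level Test level (default 0.05).
#'
#' @return One-row tibble: `statistic`, `critical_value`, `p_value`,
#'   `reject_null`, `lags_used`, `level`, `n`.
#' @export
ljung_box_test <- function(data, lags = NULL, level = 0.05) {
  x <- series_values(data, "data")
  n <- length(x)
  lags <- if (is.null(lags)) max(1L, floor(log(n))) else check_count(lags, "lags")
  if (lags < 1L || lags >= n) {
    abort("`lags` must satisfy 1 <= lags < length(data).", class = "dc_invalid_argument")
  }
  if (sd(x) == 0) {
    abort("Series is constant; autocorrelations are undefined.",
          class = "dc_undefined_metric")
  }
  bt <- Box.test(x, lag = lags, type = "Ljung-Box")
  cv <- qchisq(1 - level, df = lags)
  tibble(
    statistic = unname(bt$statistic),
    critical_value = cv,
    p_value = unname(bt$p.value),
    reject_null = unname(bt$statistic) > cv,
    lags_used = lags,
    level = level,
    n = n
  )
}

#' Choose the differencing order
#'
#' Returns the smallest `d` in `0..max_d` for which the `d`-times differenced
#' series rejects the ADF unit-root null (i.e. is judged stationary). If no
#' order passes, returns `max_d` with a warning; the result then carries
#' `attr(., "stationary") = FALSE`.
#'
#' @param data Series tibble or numeric vector.
#' @param max_d Maximum order to consider (at most 2).
#' @param ... Passed to [adf_test()] (e.g. `variant`, `lags`, `level`).
#'
#' @return Integer differencing order with attribute `stationary`.
#' @export
choose_d <- function(data, max_d = 2L, ...) {
  x <- series_values(data, "data")
  max_d <- check_count(max_d, "max_d")
  if (max_d > 2L) {
    abort("`max_d` must be at most 2.", class = "dc_invalid_argument")
  }
  for (d in 0:max_d) {
    xd <- if (d == 0L) x else diff(x, differences = d)
    rep <- adf_test(xd, ...)
    if (rep$reject_null) {
      return(structure(d, stationary = TRUE))
    }
  }
  warn(sprintf("No differencing order up to %d achieves stationarity by the ADF test.", max_d))
  structure(max_d, stationary = FALSE)
}
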