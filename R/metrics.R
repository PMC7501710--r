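#' Per-point absolute percentage errors
#'
#' Computes `PE_t = |actual_t - predicted_t| / |actual_t| * 100` for every
#' point with a non-zero actual. Zero-actual points (e.g. clinic closure days)
#' have no defined percentage error; they are kept in the output with `pe =
#' NA` and counted in the `"n_excluded"` attribute so that PE-based summaries
#' can report how many points they dropped.
#'
#' @param actual,predicted Equal-length numeric vectors or series tibbles.
#'
#' @return Tibble with columns `actual`, `predicted`, `pe`; attributes
#'   `n_used` and `n_excluded`.
#' @examples
#' percentage_errors(c(100, 200), c(90, 210)) # pe = 10, 5
#' @export
percentage_errors <- function(actual, predicted) {
  a <- series_values(actual, "actual")
  p <- series_values(predicted, "predicted")
  if (length(a) != length(p)) {
    abort("`actual` and `predicted` must have equal length.", class = "dc_invalid_argument")
  }
  if (all(a == 0)) {
    abort("All actual values are zero; percentage errors are undefined.",
          class = "dc_undefined_metric")
  }
  pe <- ifelse(a == 0, NA_real_, abs(a - p) / abs(a) * 100)
  out <- tibble(actual = a, predicted = p, pe = pe)
  attr(out, "n_used") <- sum(!is.na(pe))
  attr(out, "n_excluded") <- sum(is.na(pe))
  out
}

#' Forecast-error summary metrics
#'
#' One-row summary of a forecast/actual pair: the extreme, mean and sample
#' standard deviation of the absolute percentage errors (`pe_max`, `pe_min`,
#' `mape`, `sigma_pe`, all in percent, computed over points with non-zero
#' actuals), the raw-scale `rmse` and `mae` (computed over all points), and
#' the Pearson correlation `r` between actual and predicted. If either input
#' has zero variance, `r` is reported as `NA`.
#'
#' @param actual,predicted Equal-length numeric vectors or series tibbles,
#'   length at least 2.
#'
#' @return One-row tibble with columns `pe_max`, `pe_min`, `mape`, `sigma_pe`,
#'   `rmse`, `mae`, `r`, `n_used`.
#' @examples
#' forecast_metrics(c(100, 200, 400), c(90, 210, 400))
#' @export
forecast_metrics <- function(actual, predicted) {
  a <- series_values(actual, "actual")
  p <- series_values(predicted, "predicted")
  if (length(a) != length(p) || length(a) < 2L) {
    abort("`actual` and `predicted` must have equal length >= 2.",
          class = "dc_invalid_argument")
  }
  pe_tbl <- percentage_errors(a, p)
  pe <- pe_tbl$pe[!is.na(pe_tbl$pe)]
  err <- a - p
  r <- if (sd(a) == 0 || sd(p) == 0) {
    warn("Zero variance in actual or predicted; correlation undefined.")
    NA_real_
  } else {
    cor(a, p)
  }
  tibble(
    pe_max = max(pe),
    pe_min = min(pe),
    mape = mean(pe),
    sigma_pe = if (length(pe) > 1L) sd(pe) else NA_real_,
    rmse = sqrt(mean(err^2)),
    mae = mean(abs(err)),
    r = r,
    n_used = attr(pe_tbl, "n_used")
  )
}
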