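#' Build a demand series tibble
#'
#' The package's working representation of a univariate time series is a
#' tibble with a numeric `value` column and an optional `date` column of
#' strictly increasing calendar dates. All algorithms operate on position
#' order only; dates are carried as metadata for reporting and for
#' weekend/holiday handling.
#'
#' @param value Numeric vector of observations (e.g. visits per day).
#' @param date Optional `Date` vector of the same length, strictly increasing.
#' @param name Optional series name, stored as the `"series_name"` attribute.
#'
#' @return A tibble with columns `value` and, when supplied, `date`.
#' @examples
#' series_tbl(c(101, 98, 120), date = as.Date("2017-01-02") + 0:2)
#' @export
series_tbl <- function(value, date = NULL, name = NULL) {
  value <- as.numeric(value)
  if (length(value) < 1L) {
    abort("`value` must contain at least one observation.", class = "dc_invalid_argument")
  }
  if (!all(is.finite(value))) {
    abort("`value` must be finite throughout.", class = "dc_invalid_argument")
  }
  if (!is.null(date)) {
    date <- as.Date(date)
    if (length(date) != length(value)) {
      abort("`date` and `value` must have the same length.", class = "dc_invalid_argument")
    }
    if (anyNA(date) || any(diff(as.numeric(date)) <= 0)) {
      abort("`date` must be strictly increasing with no missing values.",
            class = "dc_invalid_argument")
    }
    out <- tibble(date = date, value = value)
  } else {
    out <- tibble(value = value)
  }
  if (!is.null(name)) attr(out, "series_name") <- name
  out
}

# Extract the numeric observations from whatever the caller passed:
# a bare numeric vector, a series tibble, or any data frame with `value`.
series_values <- function(x, arg = "x") {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.data.frame(x)) {
    if (!"value" %in% names(x)) {
      num <- vapply(x, is.numeric, logical(1))
      if (!any(num)) {
        abort(sprintf("`%s` has no `value` column and no numeric column.", arg),
              class = "dc_invalid_argument")
      }
      return(as.numeric(x[[which(num)[1L]]]))
    }
    return(as.numeric(x$value))
  }
  abort(sprintf("`%s` must be a numeric vector or a data frame.", arg),
        class = "dc_invalid_argument")
}

series_dates <- function(x) {
  if (is.data.frame(x) && "date" %in% names(x)) as.Date(x$date) else NULL
}

#' Difference a series
#'
#' Applies `d` rounds of first differencing, the standard device for removing
#' trend or unit roots before ARMA fitting. `d = 0` returns the input values
#' unchanged.
#'
#' @param data Series tibble or numeric vector.
#' @param d Non-negative integer differencing order, `d < length(data)`.
#'
#' @return Tibble with column `value` of length `length(data) - d`.
#' @examples
#' difference_series(c(1, 3, 6, 10), d = 1) # 2, 3, 4
#' @export
difference_series <- function(data, d = 1L) {
  x <- series_values(data, "data")
  d <- check_count(d, "d")
  if (d >= length(x)) {
    abort("`d` must be smaller than the series length.", class = "dc_invalid_argument")
  }
  if (d == 0L) return(tibble(value = x))
  tibble(value = diff(x, differences = d))
}

#' Invert differencing
#'
#' Maps forecasts made on the `d`-times differenced scale back to the
#' observation scale. `pre_sample` must hold the last `d` observed values of
#' the original series, in time order; the cumulative inversion then
#' reconstructs the continuation exactly, so
#' `undifference_series(difference_series(x, d), first d values of x)`
#' recovers `x[-(1:d)]`.
#'
#' @param data Differenced values (tibble or numeric vector); may be empty.
#' @param pre_sample Numeric vector of length `d` with the last observed
#'   values of the original series.
#'
#' @return Tibble with column `value`, same length as `data`.
#' @examples
#' undifference_series(c(2, 3, 4), pre_sample = 1) # 3, 6, 10
#' @export
undifference_series <- function(data, pre_sample) {
  x <- if (is.data.frame(data) && nrow(data) == 0L) numeric(0) else series_values(data, "data")
  pre_sample <- as.numeric(pre_sample)
  d <- length(pre_sample)
  if (d < 1L) {
    abort("`pre_sample` must hold the last d >= 1 observed values.",
          class = "dc_invalid_argument")
  }
  if (length(x) == 0L) return(tibble(value = numeric(0)))
  out <- diffinv(x, differences = d, xi = pre_sample)
  tibble(value = out[-seq_len(d)])
}

#' Split a series into training and verification windows
#'
#' @param data Series tibble or numeric vector.
#' @param train_size Either an integer count of training points (`> 1`) or a
#'   fraction in (0, 1). At least one verification point must remain.
#'
#' @return List with tibbles `train` and `verify`.
#' @export
split_series <- function(data, train_size = 0.8) {
  x <- series_values(data, "data")
  n <- length(x)
  n_train <- if (train_size > 0 && train_size < 1) floor(train_size * n) else as.integer(train_size)
  if (n_train < 2L || n_train >= n) {
    abort("`train_size` must leave >= 2 training and >= 1 verification points.",
          class = "dc_invalid_argument")
  }
  dates <- series_dates(data)
  mk <- function(idx) {
    if (is.null(dates)) tibble(value = x[idx]) else tibble(date = dates[idx], value = x[idx])
  }
  list(train = mk(seq_len(n_train)), verify = mk((n_train + 1L):n))
}

check_count <- function(x, arg) {
  if (length(x) != 1L || is.na(x) || x < 0 || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single non-negative integer.", arg),
          class = "dc_invalid_argument")
  }
  as.integer(x)
}
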