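#' Read a univariate series from disk
#'
#' Accepts either a two-column CSV with a header (`date,value` by default;
#' dates ISO-8601) or a headerless file with one numeric value per line.
#' Unparseable values, duplicated or non-increasing dates are rejected with
#' the offending line numbers.
#'
#' @param path File to read.
#' @param date_col,value_col Column names for the CSV layout.
#'
#' @return Series tibble (`value`, plus `date` when present).
#' @export
read_series <- function(path, date_col = "date", value_col = "value") {
  if (!file.exists(path)) {
    abort(sprintf("Input file '%s' does not exist.", path), class = "dc_input_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort(sprintf("Input file '%s' is empty.", path), class = "dc_input_error")
  }
  first_num <- suppressWarnings(as.numeric(trimws(lines[1L])))
  if (!is.na(first_num) && !grepl(",", lines[1L])) {
    # headerless value-per-line layout
    vals <- suppressWarnings(as.numeric(trimws(lines)))
    bad <- which(is.na(vals))
    if (length(bad) > 0L) {
      abort(sprintf("Unparseable value(s) at line(s) %s of '%s'.",
                    paste(bad, collapse = ", "), path), class = "dc_input_error")
    }
    return(series_tbl(vals))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!value_col %in% names(df)) {
    abort(sprintf("Column '%s' not found in '%s'.", value_col, path), class = "dc_input_error")
  }
  vals <- suppressWarnings(as.numeric(df[[value_col]]))
  bad <- which(is.na(vals))
  if (length(bad) > 0L) {
    abort(sprintf("Unparseable value(s) at data line(s) %s of '%s'.",
                  paste(bad + 1L, collapse = ", "), path), class = "dc_input_error")
  }
  if (date_col %in% names(df)) {
    dates <- as.Date(df[[date_col]])
    nas <- which(is.na(dates))
    if (length(nas) > 0L) {
      abort(sprintf("Unparseable date(s) at data line(s) %s of '%s'.",
                    paste(nas + 1L, collapse = ", "), path), class = "dc_input_error")
    }
    dup <- which(duplicated(dates))
    if (length(dup) > 0L) {
      abort(sprintf("Duplicated date(s) at data line(s) %s of '%s'.",
                    paste(dup + 1L, collapse = ", "), path), class = "dc_input_error")
    }
    if (any(diff(as.numeric(dates)) <= 0)) {
      bad2 <- which(diff(as.numeric(dates)) <= 0) + 1L
      abort(sprintf("Dates not strictly increasing at data line(s) %s of '%s'.",
                    paste(bad2 + 1L, collapse = ", "), path), class = "dc_input_error")
    }
    return(series_tbl(vals, date = dates))
  }
  series_tbl(vals)
}

#' Pipeline run configuration
#'
#' Collects every knob of [run_pipeline()] with the package defaults: an 80%
#' training split, automatic differencing, `floor(log(n))` grid bounds, BIC
#' selection, constant term on, automatic raw-scale learning constant, MAE
#' tolerance `1e-6` and at most 100 refinement rounds. Any field can be
#' overridden by name; unknown fields are rejected.
#'
#' @param ... Named overrides of the defaults.
#'
#' @return A `run_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    input = NULL,
    date_col = "date", value_col = "value",
    train_size = 0.8,
    d = "auto",
    max_p = NULL, max_q = NULL,
    criterion = "bic",
    include_constant = TRUE,
    k = NULL,
    k_scale = "raw",
    tol = 1e-6,
    max_rounds = 100L,
    residual_mode = "evolving",
    adf_variant = "none",
    seed = 1L,
    output_dir = "demandcast-run"
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown configuration field(s): %s.", paste(unknown, collapse = ", ")),
          class = "dc_invalid_argument")
  }
  cfg[names(dots)] <- dots
  if (cfg$tol <= 0) abort("`tol` must be positive.", class = "dc_invalid_argument")
  structure(cfg, class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [pipeline_config()] fields.
#' @return A `run_config` list.
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the full forecasting pipeline and write artifacts
#'
#' Reads (or accepts) a series, splits it into training and verification
#' windows, runs [hybrid_pipeline()], and writes the artifacts to
#' `config$output_dir`: `stationarity.json` (ADF and Ljung-Box reports and
#' the chosen `d`), `spec_before.json` / `spec_after.json` (model
#' coefficients), `criterion_grid.csv` (the BIC/AIC matrix, `p` in rows from
#' 0), `refine_trace.csv` (round, MAE), `forecast.csv` (step, actual, plain
#' and refined predictions) and `metrics.json` (keyed `arima` / `hybrid`).
#' Every stage decision is logged via `message()`. All randomness flows from
#' `config$seed`.
#'
#' @param config A `run_config` from [pipeline_config()] or [load_config()].
#' @param data Optional series tibble/vector; overrides `config$input`.
#'
#' @return The `hybrid_forecast` object, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), data = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(data)) {
    if (is.null(config$input)) {
      abort("Either `data` or `config$input` must be supplied.", class = "dc_input_error")
    }
    data <- read_series(config$input, config$date_col, config$value_col)
  }
  set.seed(config$seed)
  parts <- split_series(data, config$train_size)
  message(sprintf("pipeline: %d training / %d verification points",
                  nrow(parts$train), nrow(parts$verify)))
  res <- hybrid_pipeline(
    parts$train, parts$verify,
    d = config$d, max_p = config$max_p, max_q = config$max_q,
    criterion = config$criterion, include_constant = config$include_constant,
    k = config$k, k_scale = config$k_scale, tol = config$tol,
    max_rounds = config$max_rounds, residual_mode = config$residual_mode,
    adf_variant = config$adf_variant
  )
  message(sprintf("pipeline: d = %d, selected (p, q) = (%d, %d), k = %.6g, %d refinement round(s)",
                  res$d, res$grid$selected_p, res$grid$selected_q,
                  res$refit$k, res$refit$rounds_run))

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  wj <- function(x, f) jsonlite::write_json(x, out(f), auto_unbox = TRUE, digits = NA,
                                            pretty = TRUE, na = "null")
  wj(list(adf = as.list(res$adf), ljung_box = as.list(res$ljung_box), d = res$d),
     "stationarity.json")
  wj(arima_spec_list(res$fit), "spec_before.json")
  wj(arima_spec_list(res$refit$after), "spec_after.json")
  grid_df <- as.data.frame(res$grid$criterion_matrix)
  grid_df <- cbind(p = rownames(res$grid$criterion_matrix), grid_df)
  readr::write_csv(grid_df, out("criterion_grid.csv"))
  readr::write_csv(res$refit$trace, out("refine_trace.csv"))
  readr::write_csv(res$forecasts, out("forecast.csv"))
  m <- res$metrics
  wj(list(arima = as.list(m[m$model == "arima", -1L]),
          hybrid = as.list(m[m$model == "hybrid", -1L])),
     "metrics.json")
  message(sprintf("pipeline: MAPE arima = %.4f%%, hybrid = %.4f%%; artifacts in '%s'",
                  m$mape[m$model == "arima"], m$mape[m$model == "hybrid"],
                  config$output_dir))
  invisible(res)
}
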