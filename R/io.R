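# Readers and writers. All files are plain delimited text, UTF-8, '.' decimal.
# Readers validate and reject malformed input; they never coerce.

delim_for <- function(path, format = c("auto", "csv", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  if (format == "tsv") "\t" else ","
}

read_delim_strict <- function(path, sep) {
  if (!file.exists(path)) {
    stop_electrome("missing_file", sprintf("file not found: %s", path))
  }
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "", quote = "\"")
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_electrome("missing_column",
                   sprintf("%s: missing required column(s): %s",
                           path, paste(missing, collapse = ", ")))
  }
}

#' Read a voltage time series from delimited text
#'
#' Expects a header row with at least `time_s` and `voltage_uV` columns.
#' The sampling rate is inferred from the median time step and the time grid
#' is checked for strict monotonicity and uniformity (maximum relative jitter
#' 1e-6). Optional metadata columns `fruit_id`, `channel`, `stage`, `day`
#' (constant per file) are carried into the result.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension; default), `"csv"` or `"tsv"`.
#' @return A [voltage_series].
#' @export
read_voltage_series <- function(path, format = c("auto", "csv", "tsv")) {
  sep <- delim_for(path, match.arg(format))
  df <- read_delim_strict(path, sep)
  require_columns(df, c("time_s", "voltage_uV"), path)
  if (nrow(df) < 2L) {
    stop_electrome("too_few_samples",
                   sprintf("%s: need at least 2 rows to infer the sampling rate",
                           path))
  }
  t <- df$time_s
  v <- df$voltage_uV
  if (!is.numeric(t) || !all(is.finite(t))) {
    stop_electrome("nonfinite_input",
                   sprintf("%s: non-finite or non-numeric time_s (first bad row %d)",
                           path, which(!is.finite(suppressWarnings(as.numeric(t))))[1L]))
  }
  if (!is.numeric(v) || !all(is.finite(v))) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(v))))[1L]
    stop_electrome("nonfinite_input",
                   sprintf("%s: non-finite or non-numeric voltage_uV at row %d",
                           path, bad))
  }
  dt <- diff(t)
  if (any(dt <= 0)) {
    stop_electrome("nonmonotone_time",
                   sprintf("%s: time_s is not strictly increasing at row %d",
                           path, which(dt <= 0)[1L] + 1L))
  }
  step <- stats::median(dt)
  if ((max(dt) - min(dt)) > 1e-6 * step) {
    stop_electrome("nonuniform_sampling",
                   sprintf("%s: non-uniform sampling (relative jitter %.3g > 1e-6)",
                           path, (max(dt) - min(dt)) / step))
  }
  meta <- function(col, default) {
    if (col %in% names(df)) df[[col]][1L] else default
  }
  voltage_series(v, fs = 1 / step, t0 = t[1L],
                 fruit_id = as.character(meta("fruit_id", "fruit")),
                 channel = as.integer(meta("channel", 1L)),
                 stage = {
                   s <- meta("stage", NA)
                   if (is.na(s) || identical(s, "")) NULL else s
                 },
                 day = {
                   d <- meta("day", NA)
                   if (is.na(d)) NULL else as.integer(d)
                 })
}

#' Write a voltage time series to delimited text
#'
#' Writes `time_s,voltage_uV` (plus metadata columns when present) at full
#' double precision, so a write/read round trip is lossless.
#'
#' @param series A [voltage_series].
#' @param path Output path.
#' @param format `"auto"`, `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_voltage_series <- function(series, path, format = c("auto", "csv", "tsv")) {
  if (!inherits(series, "voltage_series")) {
    stop_electrome("invalid_input", "series must be a voltage_series")
  }
  sep <- delim_for(path, match.arg(format))
  t <- series_times(series)
  df <- data.frame(time_s = sprintf("%.17g", t),
                   voltage_uV = sprintf("%.17g", series$samples),
                   stringsAsFactors = FALSE)
  df$fruit_id <- series$fruit_id
  df$channel <- series$channel
  if (!is.null(series$stage)) df$stage <- series$stage
  if (!is.null(series$day)) df$day <- series$day
  ok <- tryCatch({
    utils::write.table(df, path, sep = sep, row.names = FALSE,
                       col.names = TRUE, quote = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) {
    stop_electrome("io_error", sprintf("cannot write to %s", path))
  }
  invisible(path)
}

#' Read a stage schedule file into ripening trajectories
#'
#' A stage schedule is a CSV with columns `fruit_id, stage, start_day,
#' end_day`, one row per (fruit, stage) interval; intervals are 1-based,
#' half-open `[start_day, end_day)` in experiment days.
#'
#' @param path Path to the schedule CSV.
#' @return A named list of [ripening_trajectory] objects, one per fruit.
#' @export
read_stage_schedule <- function(path) {
  df <- read_delim_strict(path, ",")
  require_columns(df, c("fruit_id", "stage", "start_day", "end_day"), path)
  split_df <- split(df, df$fruit_id)
  out <- lapply(split_df, function(d) {
    d <- d[order(d$start_day), , drop = FALSE]
    ripening_trajectory(d$fruit_id[1L],
                        stage = d$stage,
                        start_day = d$start_day,
                        end_day = d$end_day)
  })
  out[order(names(out))]
}

#' Write ripening trajectories as a stage schedule CSV
#'
#' @param trajectories A list of [ripening_trajectory] objects (or one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stage_schedule <- function(trajectories, path) {
  if (inherits(trajectories, "ripening_trajectory")) {
    trajectories <- list(trajectories)
  }
  rows <- do.call(rbind, lapply(trajectories, function(tr) {
    data.frame(fruit_id = tr$fruit_id, stage = tr$stages$stage,
               start_day = tr$stages$start_day, end_day = tr$stages$end_day,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an ApEn profile as TSV
#'
#' Columns: `fruit_id, window_start_s, window_end_s, n_samples,
#' r_absolute_uV, apen`.
#'
#' @param profile An [apen_profile][windowed_apen].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_apen_profile <- function(profile, path) {
  if (!inherits(profile, "apen_profile")) {
    stop_electrome("invalid_input", "profile must be an apen_profile")
  }
  w <- profile$windows
  df <- data.frame(fruit_id = profile$fruit_id,
                   window_start_s = sprintf("%.17g", w$start_s),
                   window_end_s = sprintf("%.17g", w$end_s),
                   n_samples = w$n_samples,
                   r_absolute_uV = sprintf("%.17g", w$r_absolute_uV),
                   apen = sprintf("%.17g", w$apen),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an ApEn profile TSV
#'
#' @param path Path to a profile written by [write_apen_profile()].
#' @param params The [apen_params] the profile was computed with (metadata
#'   only; defaults to the package defaults).
#' @return An `apen_profile`.
#' @export
read_apen_profile <- function(path, params = apen_params()) {
  df <- read_delim_strict(path, "\t")
  require_columns(df, c("fruit_id", "window_start_s", "window_end_s",
                        "n_samples", "r_absolute_uV", "apen"), path)
  windows <- data.frame(start_s = as.numeric(df$window_start_s),
                        end_s = as.numeric(df$window_end_s),
                        n_samples = as.integer(df$n_samples),
                        r_absolute_uV = as.numeric(df$r_absolute_uV),
                        apen = as.numeric(df$apen))
  if (any(!is.finite(windows$apen))) {
    stop_electrome("nonfinite_input",
                   sprintf("%s: non-finite apen at row %d", path,
                           which(!is.finite(windows$apen))[1L]))
  }
  new_apen_profile(as.character(df$fruit_id[1L]), windows, params,
                   window_len_samples = windows$n_samples[1L],
                   step_samples = NA_integer_)
}
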