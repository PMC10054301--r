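# The voltage_series container: a uniformly sampled micro-voltage recording.

#' A uniformly sampled micro-voltage time series
#'
#' The basic recording unit of the pipeline: voltage variation in micro-volts
#' sampled at a fixed rate from a pair of electrodes on the fruit surface.
#' Sample `k` (0-based) is taken at time `t0 + k / fs` seconds.
#'
#' @param samples Numeric vector of micro-volt values; finite, length >= 1.
#' @param fs Sampling rate in Hz (default 62.5, the acquisition rate this
#'   pipeline assumes).
#' @param t0 Recording start offset in seconds (default 0). Multi-day cohorts
#'   use `t0 = (day - 1) * 86400` so window times are absolute within a fruit.
#' @param fruit_id Identifier of the recorded fruit.
#' @param channel Acquisition channel number (provenance metadata).
#' @param stage Optional ripening stage label at recording start
#'   (one of `r paste(stage_levels(), collapse = ", ")`; `"BR"` accepted).
#' @param day Optional 1-based experiment day of the acquisition.
#' @return An object of class `voltage_series`.
#' @export
#' @examples
#' vs <- voltage_series(sin(seq_len(500)), fs = 62.5, fruit_id = "fruit01")
#' vs
voltage_series <- function(samples, fs = 62.5, t0 = 0, fruit_id = "fruit",
                           channel = 1L, stage = NULL, day = NULL) {
  check_finite_numeric(samples, "samples")
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop_electrome("invalid_input", "fs must be a positive sampling rate in Hz")
  }
  if (length(t0) != 1L || !is.finite(t0)) {
    stop_electrome("invalid_input", "t0 must be a finite offset in seconds")
  }
  if (!is.null(stage)) stage <- normalize_stage(stage)
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         t0 = as.numeric(t0), fruit_id = as.character(fruit_id),
         channel = as.integer(channel), stage = stage,
         day = if (is.null(day)) NULL else as.integer(day)),
    class = "voltage_series"
  )
}

#' @export
print.voltage_series <- function(x, ...) {
  dur <- length(x$samples) / x$fs
  cat(sprintf("<voltage_series> %s%s: %d samples @ %g Hz (%.1f s)%s\n",
              x$fruit_id,
              if (!is.null(x$day)) sprintf(" day %d", x$day) else "",
              length(x$samples), x$fs, dur,
              if (!is.null(x$stage)) sprintf(", stage %s", x$stage) else ""))
  invisible(x)
}

#' @export
length.voltage_series <- function(x) length(x$samples)

#' Sample times of a voltage series
#'
#' @param series A [voltage_series].
#' @return Numeric vector of times in seconds, `t0 + k / fs` for 0-based `k`.
#' @export
series_times <- function(series) {
  if (!inherits(series, "voltage_series")) {
    stop_electrome("invalid_input", "series must be a voltage_series")
  }
  series$t0 + (seq_along(series$samples) - 1) / series$fs
}

#' Light preprocessing: drift removal and decimation
#'
#' Optional moving-average detrending (a software analogue of high-pass
#' conditioning: the centered, edge-truncated moving mean over a long window
#' is subtracted, removing slow baseline drift) followed by optional
#' keep-every-kth decimation with the sampling rate updated to `fs / k`.
#' With both options disabled this is the identity.
#'
#' @param series A [voltage_series].
#' @param detrend_window_s Moving-average window in seconds (positive), or
#'   `NULL` to skip detrending.
#' @param decimate_by Keep every k-th sample (integer >= 1), or `NULL`/1 to
#'   skip. Decimation that would leave fewer than 64 samples is an error.
#' @return A new [voltage_series] with metadata preserved.
#' @export
#' @examples
#' vs <- voltage_series(seq(0, 10, length.out = 1000) + sin(1:1000))
#' flat <- preprocess_series(vs, detrend_window_s = 20)
preprocess_series <- function(series, detrend_window_s = NULL,
                              decimate_by = NULL) {
  if (!inherits(series, "voltage_series")) {
    stop_electrome("invalid_input", "series must be a voltage_series")
  }
  x <- series$samples
  fs <- series$fs
  if (!is.null(detrend_window_s)) {
    if (length(detrend_window_s) != 1L || !is.finite(detrend_window_s) ||
        detrend_window_s <= 0) {
      stop_electrome("invalid_input", "detrend_window_s must be positive")
    }
    w <- max(1L, as.integer(round(detrend_window_s * fs)))
    h <- w %/% 2L
    n <- length(x)
    # centered moving mean; near the edges the half-width shrinks
    # symmetrically, which keeps the window centered on each sample and
    # removes a purely linear trend exactly
    i <- seq_len(n)
    hi_half <- pmin(h, i - 1L, n - i)
    cs <- c(0, cumsum(x))
    lo <- i - hi_half
    hi <- i + hi_half
    ma <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    x <- x - ma
  }
  if (!is.null(decimate_by) && decimate_by != 1L) {
    k <- decimate_by
    if (length(k) != 1L || !is.finite(k) || k < 1 || k != as.integer(k)) {
      stop_electrome("invalid_input", "decimate_by must be an integer >= 1")
    }
    k <- as.integer(k)
    x <- x[seq(1L, length(x), by = k)]
    fs <- fs / k
    if (length(x) < 64L) {
      stop_electrome("too_few_samples",
                     sprintf("decimation by %d leaves %d samples (< 64)",
                             k, length(x)))
    }
  }
  voltage_series(x, fs = fs, t0 = series$t0, fruit_id = series$fruit_id,
                 channel = series$channel, stage = series$stage,
                 day = series$day)
}
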