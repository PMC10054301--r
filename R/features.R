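# Per-window signal features. ApEn is the feature of interest; the rest are
# simple moment/autocorrelation descriptors that give the classifier a
# realistic multivariate input.

feature_names <- function() {
  c("apen", "sd_uV", "skewness", "excess_kurtosis",
    "mean_abs_successive_diff", "lag1_autocorrelation")
}

# All six features of one window. Constant windows use the degenerate policy:
# every shape feature (and ApEn, via r = 0) is 0.
window_features <- function(seg, params, r_absolute = NULL) {
  s <- pop_sd(seg)
  if (s == 0) {
    return(c(apen = 0, sd_uV = 0, skewness = 0, excess_kurtosis = 0,
             mean_abs_successive_diff = 0, lag1_autocorrelation = 0))
  }
  n <- length(seg)
  lag1 <- stats::cor(seg[-n], seg[-1L])
  if (!is.finite(lag1)) lag1 <- 0
  c(apen = apen(seg, params, r_absolute = r_absolute)$value,
    sd_uV = s,
    skewness = pop_skewness(seg),
    excess_kurtosis = pop_excess_kurtosis(seg),
    mean_abs_successive_diff = mean(abs(diff(seg))),
    lag1_autocorrelation = lag1)
}

#' Extract per-window features from a recording
#'
#' Slides the same windows as [windowed_apen()] and computes, per window:
#' ApEn, population standard deviation, skewness, excess kurtosis, mean
#' absolute successive difference, and lag-1 Pearson autocorrelation.
#' Constant windows get all features defined as 0.
#'
#' @inheritParams windowed_apen
#' @param stage Optional stage label attached to every row (taken from the
#'   series metadata when present).
#' @return A data frame with one row per window: `fruit_id, start_s, end_s,
#'   stage`, then the six feature columns.
#' @export
extract_features <- function(series, params = apen_params(),
                             window_len_samples = 2048L,
                             step_samples = window_len_samples,
                             stage = NULL) {
  if (!inherits(series, "voltage_series")) series <- voltage_series(series)
  if (is.null(stage)) stage <- if (is.null(series$stage)) NA_character_
                               else series$stage
  w <- as.integer(window_len_samples)
  s <- as.integer(step_samples)
  if (!is.finite(w) || w < 64L) {
    stop_electrome("invalid_input", "window_len_samples must be >= 64")
  }
  if (!is.finite(s) || s < 1L) {
    stop_electrome("invalid_input", "step_samples must be >= 1")
  }
  x <- series$samples
  n <- length(x)
  if (n < w) {
    stop_electrome("series_too_short",
                   sprintf("series of %d samples is shorter than one window (%d)",
                           n, w))
  }
  n_win <- (n - w) %/% s + 1L
  starts <- (seq_len(n_win) - 1L) * s + 1L
  feats <- t(vapply(starts, function(i0) {
    window_features(x[i0:(i0 + w - 1L)], params)
  }, numeric(6L)))
  colnames(feats) <- feature_names()
  out <- data.frame(fruit_id = series$fruit_id,
                    start_s = series$t0 + (starts - 1L) / series$fs,
                    end_s = series$t0 + (starts - 1L + w) / series$fs,
                    stage = stage, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(feats))
}

#' Feature table for a whole simulated cohort
#'
#' [extract_features()] per acquisition, with the stage label taken from each
#' acquisition's metadata, concatenated across fruits and days.
#'
#' @param cohort An `electrome_cohort`.
#' @inheritParams windowed_apen
#' @return A feature data frame (see [extract_features()]).
#' @export
cohort_features <- function(cohort, params = apen_params(),
                            window_len_samples = 2048L,
                            step_samples = window_len_samples) {
  if (!inherits(cohort, "electrome_cohort")) {
    stop_electrome("invalid_input", "cohort must be an electrome_cohort")
  }
  out <- do.call(rbind, lapply(cohort$series, function(s) {
    extract_features(s, params = params,
                     window_len_samples = window_len_samples,
                     step_samples = step_samples)
  }))
  rownames(out) <- NULL
  out
}
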