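# Sliding-window ApEn profiles, per-stage summaries and dip detection.

new_apen_profile <- function(fruit_id, windows, params, window_len_samples,
                             step_samples) {
  structure(
    list(fruit_id = fruit_id, windows = windows, params = params,
         window_len_samples = window_len_samples,
         step_samples = step_samples),
    class = "apen_profile"
  )
}

#' @export
print.apen_profile <- function(x, ...) {
  cat(sprintf("<apen_profile> %s: %d windows of %s samples, ApEn in [%.3f, %.3f]\n",
              x$fruit_id, nrow(x$windows),
              paste(unique(x$window_len_samples), collapse = "/"),
              min(x$windows$apen), max(x$windows$apen)))
  invisible(x)
}

#' Windowed approximate entropy profile
#'
#' Slides a window of `window_len_samples` along the series in steps of
#' `step_samples` (defaulting to non-overlapping windows) and computes ApEn
#' independently in each window, with the tolerance taken from that window's
#' own standard deviation unless a global `r_absolute` is supplied. Trailing
#' samples that do not fill a window are dropped, so the number of windows is
#' `floor((N - window_len) / step) + 1`.
#'
#' @param series A [voltage_series] or numeric vector.
#' @param params An [apen_params].
#' @param window_len_samples Window length in samples, `>= 64` (default 2048,
#'   about 33 s at 62.5 Hz).
#' @param step_samples Step between window starts (default = window length,
#'   i.e. non-overlapping windows).
#' @param r_absolute Optional global tolerance in micro-volts applied to every
#'   window instead of the per-window `r_factor * SD` (sensitivity analyses).
#' @return An object of class `apen_profile`: the window table
#'   (`start_s, end_s, n_samples, r_absolute_uV, apen`) plus the parameters
#'   used.
#' @export
#' @examples
#' vs <- simulate_acquisition("f1", stage_signal_spec("MG", 0.6),
#'                            duration_s = 60, seed = 1)
#' windowed_apen(vs, window_len_samples = 256)
windowed_apen <- function(series, params = apen_params(),
                          window_len_samples = 2048L,
                          step_samples = window_len_samples,
                          r_absolute = NULL) {
  if (!inherits(series, "voltage_series")) {
    series <- voltage_series(series)
  }
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
  rows <- lapply(starts, function(i0) {
    seg <- x[i0:(i0 + w - 1L)]
    res <- apen(seg, params, r_absolute = r_absolute)
    data.frame(start_s = series$t0 + (i0 - 1L) / series$fs,
               end_s = series$t0 + (i0 - 1L + w) / series$fs,
               n_samples = w,
               r_absolute_uV = res$r_absolute,
               apen = res$value)
  })
  new_apen_profile(series$fruit_id, do.call(rbind, rows), params, w, s)
}

#' Concatenate per-acquisition profiles of one fruit
#'
#' Multi-day recordings are profiled one acquisition at a time; this binds the
#' daily profiles of a single fruit into one profile ordered by window start
#' time, for dip detection across the whole ripening course.
#'
#' @param profiles A list of `apen_profile` objects sharing one `fruit_id`.
#' @return A single `apen_profile`.
#' @export
bind_profiles <- function(profiles) {
  if (inherits(profiles, "apen_profile")) return(profiles)
  if (length(profiles) == 0L) {
    stop_electrome("invalid_input", "no profiles to bind")
  }
  if (!all(vapply(profiles, inherits, logical(1), "apen_profile"))) {
    stop_electrome("invalid_input", "profiles must be apen_profile objects")
  }
  ids <- unique(vapply(profiles, function(p) p$fruit_id, character(1)))
  if (length(ids) != 1L) {
    stop_electrome("invalid_input",
                   sprintf("profiles span several fruits: %s",
                           paste(ids, collapse = ", ")))
  }
  windows <- do.call(rbind, lapply(profiles, function(p) p$windows))
  windows <- windows[order(windows$start_s), , drop = FALSE]
  rownames(windows) <- NULL
  p1 <- profiles[[1L]]
  new_apen_profile(ids, windows, p1$params, p1$window_len_samples,
                   p1$step_samples)
}

# Midpoint experiment day of each profile window (1-based; days are 86400 s).
window_days <- function(profile) {
  floor((profile$windows$start_s + profile$windows$end_s) / 2 / 86400) + 1
}

#' Per-stage summary of ApEn profiles
#'
#' Assigns each profile window to the ripening stage covering its midpoint
#' (at day resolution) and pools ApEn values within stage across fruits.
#' Windows whose midpoint falls outside every stage interval are counted and
#' reported in the `n_unassigned` attribute, never dropped silently.
#'
#' @param profiles A list of `apen_profile` objects (or one).
#' @param trajectories Named list of [ripening_trajectory], one per fruit
#'   appearing in `profiles`.
#' @return A data frame `stage, mean_apen, sd_apen, n_windows, n_fruits`, in
#'   canonical stage order, with attribute `n_unassigned`.
#' @export
stage_summary <- function(profiles, trajectories) {
  if (inherits(profiles, "apen_profile")) profiles <- list(profiles)
  if (length(profiles) == 0L) {
    stop_electrome("invalid_input", "profiles is empty")
  }
  if (inherits(trajectories, "ripening_trajectory")) {
    trajectories <- list(trajectories)
  }
  traj_ids <- vapply(trajectories, function(tr) tr$fruit_id, character(1))
  names(trajectories) <- traj_ids
  rows <- do.call(rbind, lapply(profiles, function(p) {
    if (!p$fruit_id %in% traj_ids) {
      stop_electrome("missing_trajectory",
                     sprintf("no trajectory for fruit %s", p$fruit_id))
    }
    tr <- trajectories[[p$fruit_id]]
    data.frame(fruit_id = p$fruit_id,
               stage = stage_for_day(tr, window_days(p)),
               apen = p$windows$apen, stringsAsFactors = FALSE)
  }))
  n_unassigned <- sum(is.na(rows$stage))
  rows <- rows[!is.na(rows$stage), , drop = FALSE]
  out <- do.call(rbind, c(
    list(data.frame(stage = character(0), mean_apen = numeric(0),
                    sd_apen = numeric(0), n_windows = integer(0),
                    n_fruits = integer(0), stringsAsFactors = FALSE)),
    lapply(split(rows, rows$stage), function(g) {
      data.frame(stage = g$stage[1L], mean_apen = mean(g$apen),
                 sd_apen = pop_sd(g$apen), n_windows = nrow(g),
                 n_fruits = length(unique(g$fruit_id)),
                 stringsAsFactors = FALSE)
    })))
  out <- out[order(match(out$stage, stage_levels())), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unassigned") <- n_unassigned
  out
}

# Running median with truncated edges: value i is the median over the windows
# clipped to the series bounds.
running_median <- function(v, k) {
  h <- (k - 1L) %/% 2L
  n <- length(v)
  vapply(seq_len(n), function(i) {
    stats::median(v[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Detect the entropy dip of a ripening profile
#'
#' Smooths the windowed ApEn values with a running median (robust to
#' spike-contaminated windows), takes the global minimum of the smoothed
#' profile as the dip (earliest window on ties), and reports the medians of
#' the smoothed values before and after it. When a trajectory is supplied the
#' stage containing the dip window is reported, which is how the pipeline
#' checks that a fruit's entropy minimum falls in the breaker stage.
#'
#' @param profile An `apen_profile` with at least `2 * smooth_k` windows.
#' @param smooth_k Odd running-median width (default 5).
#' @param trajectory Optional [ripening_trajectory] for the same fruit.
#' @return An object of class `dip_report`: `fruit_id`, `dip_window`
#'   (`c(start_s, end_s)`), `dip_index`, `dip_value` (smoothed ApEn at the
#'   dip), `pre_dip_median`, `post_dip_median` (`NA` when the dip is at a
#'   boundary), and `dip_in_stage` (`NA` without a trajectory).
#' @export
detect_dip <- function(profile, smooth_k = 5L, trajectory = NULL) {
  if (!inherits(profile, "apen_profile")) {
    stop_electrome("invalid_input", "profile must be an apen_profile")
  }
  k <- as.integer(smooth_k)
  if (!is.finite(k) || k < 1L || k %% 2L == 0L) {
    stop_electrome("invalid_input", "smooth_k must be a positive odd integer")
  }
  v <- profile$windows$apen
  if (length(v) < 2L * k) {
    stop_electrome("too_few_windows",
                   sprintf("need at least 2 * smooth_k = %d windows, got %d",
                           2L * k, length(v)))
  }
  sm <- running_median(v, k)
  i <- which.min(sm)  # which.min returns the earliest tie
  pre <- if (i > 1L) stats::median(sm[seq_len(i - 1L)]) else NA_real_
  post <- if (i < length(sm)) stats::median(sm[(i + 1L):length(sm)]) else NA_real_
  dip_stage <- NA_character_
  if (!is.null(trajectory)) {
    if (!inherits(trajectory, "ripening_trajectory")) {
      stop_electrome("invalid_input", "trajectory must be a ripening_trajectory")
    }
    mid_day <- floor((profile$windows$start_s[i] + profile$windows$end_s[i]) /
                       2 / 86400) + 1
    dip_stage <- stage_for_day(trajectory, mid_day)
  }
  structure(
    list(fruit_id = profile$fruit_id,
         dip_window = c(start_s = profile$windows$start_s[i],
                        end_s = profile$windows$end_s[i]),
         dip_index = i,
         dip_value = sm[i],
         pre_dip_median = pre,
         post_dip_median = post,
         dip_in_stage = dip_stage,
         smooth_k = k),
    class = "dip_report"
  )
}

#' @export
print.dip_report <- function(x, ...) {
  cat(sprintf("<dip_report> %s: dip at window %d (t = %.0f..%.0f s), ApEn %.4f%s\n",
              x$fruit_id, x$dip_index, x$dip_window[1L], x$dip_window[2L],
              x$dip_value,
              if (!is.na(x$dip_in_stage)) sprintf(", stage %s", x$dip_in_stage)
              else ""))
  cat(sprintf("  pre-dip median %.4f, post-dip median %.4f\n",
              x$pre_dip_median, x$post_dip_median))
  invisible(x)
}

#' Profile every fruit of a simulated cohort
#'
#' Convenience wrapper: windowed ApEn per acquisition, then daily profiles
#' bound per fruit.
#'
#' @param cohort An `electrome_cohort` from [simulate_cohort()].
#' @param params An [apen_params].
#' @param window_len_samples,step_samples Passed to [windowed_apen()].
#' @return Named list of `apen_profile`, one per fruit.
#' @export
profile_cohort <- function(cohort, params = apen_params(),
                           window_len_samples = 2048L,
                           step_samples = window_len_samples) {
  if (!inherits(cohort, "electrome_cohort")) {
    stop_electrome("invalid_input", "cohort must be an electrome_cohort")
  }
  ids <- vapply(cohort$series, function(s) s$fruit_id, character(1))
  by_fruit <- split(cohort$series, ids)
  lapply(by_fruit, function(acqs) {
    bind_profiles(lapply(acqs, windowed_apen, params = params,
                         window_len_samples = window_len_samples,
                         step_samples = step_samples))
  })
}
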