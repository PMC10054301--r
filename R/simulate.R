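# Synthetic fruit electrome cohorts.
#
# The generator emulates the statistical structure the analysis assumes:
# stage-dependent signal regularity (irregular at mature green, markedly more
# regular at breaker, partially irregular again at light red), per-fruit
# variation in stage transition times, micro-volt amplitudes, slow baseline
# drift and sparse transient spikes. It makes no attempt at biophysical
# realism (no membrane or ion-channel model).

#' The MIX(p) regularity-tunable benchmark process
#'
#' Blends a deterministic period-12 sinusoid with iid uniform noise: with
#' probability `p` a sample is replaced by a `Uniform(-sqrt(3), sqrt(3))`
#' draw (unit variance), otherwise it is `sqrt(2) * sin(2 * pi * j / 12)`
#' (also unit variance). Expected ApEn increases with `p`, which makes the
#' family the standard testbed for regularity statistics: `p = 0` is fully
#' periodic, `p = 1` is white noise.
#'
#' @param n Number of samples (>= 1).
#' @param p Irregularity fraction in `[0, 1]`.
#' @param seed Integer seed; `NULL` draws from the current RNG state.
#' @return Numeric vector of length `n`, unit variance in expectation.
#' @export
#' @examples
#' apen(mix_process(500, 0, seed = 1))$value <
#'   apen(mix_process(500, 1, seed = 1))$value
mix_process <- function(n, p, seed = NULL) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != as.integer(n)) {
    stop_electrome("invalid_input", "n must be a positive integer")
  }
  if (length(p) != 1L || !is.finite(p) || p < 0 || p > 1) {
    stop_electrome("invalid_input", "p must lie in [0, 1]")
  }
  n <- as.integer(n)
  j <- seq_len(n)
  x <- sqrt(2) * sin(2 * pi * j / 12)
  with_seed(seed, {
    z <- as.numeric(runif(n) < p)
    y <- runif(n, -sqrt(3), sqrt(3))
    (1 - z) * x + z * y
  })
}

#' Per-stage signal specification for the synthetic generator
#'
#' @param stage Ripening stage label the spec applies to.
#' @param mix_p Irregularity fraction of the [mix_process()] core, in
#'   `[0, 1]`; higher means higher expected ApEn.
#' @param amplitude_uV Signal amplitude in micro-volts (the unit-variance core
#'   is multiplied by this).
#' @param drift_uV_per_hour Slow linear baseline drift rate.
#' @param spike_rate_per_hour Poisson rate of transient biphasic spikes
#'   (depolarization-like events) per hour of synthesized signal.
#' @param spike_amplitude_uV Deflection of each spike (one sample up, the
#'   next down).
#' @return An object of class `stage_signal_spec`.
#' @export
stage_signal_spec <- function(stage, mix_p, amplitude_uV = 10,
                              drift_uV_per_hour = 2,
                              spike_rate_per_hour = 2,
                              spike_amplitude_uV = 50) {
  stage <- normalize_stage(stage)
  if (length(mix_p) != 1L || !is.finite(mix_p) || mix_p < 0 || mix_p > 1) {
    stop_electrome("invalid_input", "mix_p must lie in [0, 1]")
  }
  if (!is.finite(amplitude_uV) || amplitude_uV <= 0) {
    stop_electrome("invalid_input", "amplitude_uV must be positive")
  }
  if (!is.finite(spike_rate_per_hour) || spike_rate_per_hour < 0) {
    stop_electrome("invalid_input", "spike_rate_per_hour must be >= 0")
  }
  if (!is.finite(spike_amplitude_uV) || spike_amplitude_uV <= 0) {
    stop_electrome("invalid_input", "spike_amplitude_uV must be positive")
  }
  structure(
    list(stage = stage, mix_p = mix_p, amplitude_uV = amplitude_uV,
         drift_uV_per_hour = drift_uV_per_hour,
         spike_rate_per_hour = spike_rate_per_hour,
         spike_amplitude_uV = spike_amplitude_uV),
    class = "stage_signal_spec"
  )
}

#' Default per-stage signal specifications
#'
#' Regularity levels chosen once to reproduce, qualitatively, the published
#' per-fruit entropy pattern through ripening: irregular at mature green
#' (`mix_p = 0.6`), a pronounced regularity dip at breaker (`mix_p = 0.2`),
#' and a partial recovery at light red (`mix_p = 0.5`). Only the orderings
#' MG > B and LR > B are treated as ground truth; absolute levels are not.
#' Amplitude, drift and spike settings are identical across stages, so
#' stage differences are carried by regularity alone.
#'
#' @return Named list of [stage_signal_spec] objects for MG, B, LR.
#' @export
default_stage_specs <- function() {
  list(MG = stage_signal_spec("MG", mix_p = 0.6),
       B  = stage_signal_spec("B",  mix_p = 0.2),
       LR = stage_signal_spec("LR", mix_p = 0.5))
}

#' Cohort simulation settings
#'
#' @param n_fruits Number of fruits (default 20: five repetitions of four
#'   fruits, the cohort layout this pipeline assumes).
#' @param stage_specs Named list of [stage_signal_spec] for the stages each
#'   fruit passes through, in ripening order (default [default_stage_specs()]).
#' @param stage_duration_days Named list, per stage, of `c(mean, sd)` in days
#'   for a truncated-positive normal duration; realized durations are rounded
#'   to whole days with a 1-day floor. Defaults: MG 4 +/- 1, B 2 +/- 0.7,
#'   LR 2 +/- 0.7.
#' @param fs Sampling rate in Hz (default 62.5).
#' @param seconds_per_day Seconds of signal synthesized per simulated day.
#'   The default, 1200 s (20 min), is a desk-scale stand-in for a full 24 h
#'   acquisition; pass `86400` for full days.
#' @param master_seed Integer master seed; every fruit and day derives its own
#'   stream via [child_seed()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_fruits = 20L,
                          stage_specs = default_stage_specs(),
                          stage_duration_days = list(MG = c(4, 1),
                                                     B = c(2, 0.7),
                                                     LR = c(2, 0.7)),
                          fs = 62.5,
                          seconds_per_day = 1200,
                          master_seed = 1L) {
  if (!is.finite(n_fruits) || n_fruits < 1 || n_fruits != as.integer(n_fruits)) {
    stop_electrome("invalid_input", "n_fruits must be a positive integer")
  }
  if (length(stage_specs) < 1L ||
      !all(vapply(stage_specs, inherits, logical(1), "stage_signal_spec"))) {
    stop_electrome("invalid_input",
                   "stage_specs must be a list of stage_signal_spec objects")
  }
  stages <- vapply(stage_specs, function(s) s$stage, character(1))
  names(stage_specs) <- stages
  if (any(diff(match(stages, stage_levels())) <= 0)) {
    stop_electrome("invalid_input",
                   "stage_specs must be in canonical ripening order")
  }
  missing_dur <- setdiff(stages, names(stage_duration_days))
  if (length(missing_dur) > 0L) {
    stop_electrome("invalid_input",
                   sprintf("stage_duration_days missing stage(s): %s",
                           paste(missing_dur, collapse = ", ")))
  }
  for (s in stages) {
    d <- stage_duration_days[[s]]
    if (length(d) != 2L || !all(is.finite(d)) || d[1L] <= 0 || d[2L] < 0) {
      stop_electrome("invalid_input",
                     sprintf("stage_duration_days$%s must be c(mean > 0, sd >= 0)", s))
    }
  }
  if (!is.finite(fs) || fs <= 0) {
    stop_electrome("invalid_input", "fs must be positive")
  }
  if (!is.finite(seconds_per_day) || seconds_per_day * fs < 64) {
    stop_electrome("invalid_input",
                   "seconds_per_day too small: need at least 64 samples per day")
  }
  structure(
    list(n_fruits = as.integer(n_fruits), stage_specs = stage_specs,
         stage_duration_days = stage_duration_days[stages],
         fs = as.numeric(fs), seconds_per_day = as.numeric(seconds_per_day),
         master_seed = as.integer(master_seed)),
    class = "cohort_config"
  )
}

#' Simulate one acquisition (one fruit-day of signal)
#'
#' Synthesizes `ceiling(duration_s * fs)` samples:
#' `amplitude_uV * MIX(mix_p)` plus a linear drift of `drift_uV_per_hour`
#' and Poisson-timed biphasic spikes (one sample up by `spike_amplitude_uV`,
#' the next down by the same amount). Deterministic given `seed`.
#'
#' @param fruit_id Fruit identifier attached to the series.
#' @param spec A [stage_signal_spec]; its `stage` labels the series.
#' @param duration_s Duration of synthesized signal in seconds;
#'   `duration_s * fs` must be at least 64 samples.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed (or `NULL` for the current RNG state).
#' @param t0 Start time in seconds.
#' @param day Optional 1-based experiment day label.
#' @return A [voltage_series].
#' @export
#' @examples
#' vs <- simulate_acquisition("fruit01", stage_signal_spec("MG", 0.6),
#'                            duration_s = 60, seed = 7)
simulate_acquisition <- function(fruit_id, spec, duration_s, fs = 62.5,
                                 seed = NULL, t0 = 0, day = NULL) {
  if (!inherits(spec, "stage_signal_spec")) {
    stop_electrome("invalid_input", "spec must be a stage_signal_spec")
  }
  if (!is.finite(duration_s) || duration_s <= 0) {
    stop_electrome("invalid_input", "duration_s must be positive")
  }
  n <- as.integer(ceiling(duration_s * fs))
  if (n < 64L) {
    stop_electrome("too_few_samples",
                   sprintf("acquisition of %d samples is below the 64-sample minimum", n))
  }
  samples <- with_seed(seed, {
    core <- spec$amplitude_uV * mix_process(n, spec$mix_p, seed = NULL)
    t_hours <- (seq_len(n) - 1) / fs / 3600
    x <- core + spec$drift_uV_per_hour * t_hours
    n_spikes <- rpois(1L, spec$spike_rate_per_hour * duration_s / 3600)
    if (n_spikes > 0L && n >= 2L) {
      pos <- sample.int(n - 1L, n_spikes, replace = TRUE)
      for (k in pos) {
        x[k] <- x[k] + spec$spike_amplitude_uV
        x[k + 1L] <- x[k + 1L] - spec$spike_amplitude_uV
      }
    }
    x
  })
  voltage_series(samples, fs = fs, t0 = t0, fruit_id = fruit_id,
                 stage = spec$stage, day = day)
}

#' Simulate a ripening cohort
#'
#' For each fruit, stage durations are drawn independently from the
#' configured truncated-positive normals (rounded to whole days, 1-day
#' minimum) using a child seed derived from the master seed and fruit index;
#' then one acquisition per simulated day is synthesized under that day's
#' stage spec with a child seed derived from (master seed, fruit, day).
#' Regenerating with the same config reproduces the cohort exactly.
#'
#' @param config A [cohort_config].
#' @return An object of class `electrome_cohort`: a list with `series` (a
#'   list of [voltage_series], one per fruit-day, named `fruitNN_dayDDD`),
#'   `trajectories` (named list of [ripening_trajectory]), and `config`.
#' @export
#' @examples
#' co <- simulate_cohort(cohort_config(n_fruits = 2, seconds_per_day = 60,
#'                                     master_seed = 7))
#' co$trajectories[[1]]
simulate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    stop_electrome("invalid_input", "config must be a cohort_config")
  }
  stages <- names(config$stage_specs)
  series <- list()
  trajectories <- list()
  for (f in seq_len(config$n_fruits)) {
    fid <- sprintf("fruit%02d", f)
    dur_days <- with_seed(child_seed(config$master_seed, f, 0L), {
      vapply(stages, function(s) {
        ms <- config$stage_duration_days[[s]]
        d <- rnorm(1L, ms[1L], ms[2L])
        while (d <= 0) d <- rnorm(1L, ms[1L], ms[2L])
        max(1L, as.integer(round(d)))
      }, integer(1))
    })
    ends <- 1L + cumsum(dur_days)
    starts <- c(1L, ends[-length(ends)])
    traj <- ripening_trajectory(fid, stage = stages, start_day = starts,
                                end_day = ends)
    trajectories[[fid]] <- traj
    for (day in seq_len(sum(dur_days))) {
      st <- stage_for_day(traj, day)
      acq <- simulate_acquisition(
        fid, config$stage_specs[[st]], duration_s = config$seconds_per_day,
        fs = config$fs, seed = child_seed(config$master_seed, f, day),
        t0 = (day - 1) * 86400, day = day
      )
      series[[sprintf("%s_day%03d", fid, day)]] <- acq
    }
  }
  structure(list(series = series, trajectories = trajectories,
                 config = config),
            class = "electrome_cohort")
}

#' @export
print.electrome_cohort <- function(x, ...) {
  cat(sprintf("<electrome_cohort> %d fruits, %d fruit-day acquisitions @ %g Hz\n",
              length(x$trajectories), length(x$series), x$config$fs))
  invisible(x)
}
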