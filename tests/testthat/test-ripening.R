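# Windowed profiling, stage summaries, dip detection, transition timing.

test_that("windowing conservation: n_windows = floor((N - w)/step) + 1", {
  x <- voltage_series(mix_process(1280, 0.5, seed = 1), fs = 62.5)
  p <- windowed_apen(x, window_len_samples = 128, step_samples = 128)
  expect_equal(nrow(p$windows), 10L)
  expect_true(all(p$windows$n_samples == 128L))

  p2 <- windowed_apen(x, window_len_samples = 128, step_samples = 37)
  expect_equal(nrow(p2$windows), (1280L - 128L) %/% 37L + 1L)

  expect_error(windowed_apen(voltage_series(runif(100)),
                             window_len_samples = 128),
               class = "electromeR_series_too_short")
  expect_error(windowed_apen(x, window_len_samples = 32),
               class = "electromeR_invalid_input")
})

test_that("constant series profiles to all-zero ApEn", {
  p <- windowed_apen(voltage_series(rep(4, 640)), window_len_samples = 128)
  expect_true(all(p$windows$apen == 0))
  expect_true(all(p$windows$r_absolute_uV == 0))
})

test_that("noise windows score above periodic windows in one recording", {
  set.seed(31)
  x <- c(runif(3 * 256), rep(c(0, 1), 3 * 128))
  p <- windowed_apen(voltage_series(x), window_len_samples = 256)
  a <- p$windows$apen
  expect_true(min(a[1:3]) > max(a[4:6]))
})

test_that("per-window tolerance varies with window SD; global override fixes it", {
  x <- voltage_series(c(mix_process(256, 1, seed = 1) * 5,
                        mix_process(256, 1, seed = 2) * 50))
  p <- windowed_apen(x, window_len_samples = 256)
  expect_gt(p$windows$r_absolute_uV[2], 5 * p$windows$r_absolute_uV[1])
  pg <- windowed_apen(x, window_len_samples = 256, r_absolute = 2)
  expect_true(all(pg$windows$r_absolute_uV == 2))
})

test_that("stage summary pools windows by the stage at their midpoint", {
  # single stage, constant signal: mean 0, SD 0
  vs <- voltage_series(rep(1, 640), fs = 62.5, fruit_id = "f1", day = 1L,
                       t0 = 0)
  prof <- windowed_apen(vs, window_len_samples = 128)
  tr <- ripening_trajectory("f1", "MG", 1, 3)
  s <- stage_summary(list(prof), list(tr))
  expect_equal(s$stage, "MG")
  expect_equal(s$mean_apen, 0)
  expect_equal(s$sd_apen, 0)
  expect_equal(s$n_windows, 5L)
  expect_equal(attr(s, "n_unassigned"), 0L)

  expect_error(stage_summary(list(), list(tr)),
               class = "electromeR_invalid_input")
  expect_error(stage_summary(list(prof), list()),
               class = "electromeR_missing_trajectory")
})

test_that("windows outside every stage interval are counted as unassigned", {
  vs <- voltage_series(runif(640), fs = 62.5, fruit_id = "f1",
                       t0 = 5 * 86400)  # day 6, beyond the trajectory
  prof <- windowed_apen(vs, window_len_samples = 128)
  tr <- ripening_trajectory("f1", "MG", 1, 3)
  s <- stage_summary(list(prof), list(tr))
  expect_equal(attr(s, "n_unassigned"), 5L)
  expect_equal(nrow(s), 0L)
})

test_that("stage summary is invariant to fruit order", {
  co <- simulate_cohort(cohort_config(n_fruits = 3, seconds_per_day = 30,
                                      master_seed = 4))
  profs <- profile_cohort(co, window_len_samples = 256)
  s1 <- stage_summary(profs, co$trajectories)
  s2 <- stage_summary(rev(profs), rev(co$trajectories))
  expect_equal(s1, s2, ignore_attr = TRUE)
})

test_that("dip detection finds the smoothed global minimum", {
  mk_profile <- function(vals) {
    w <- data.frame(start_s = (seq_along(vals) - 1) * 10,
                    end_s = seq_along(vals) * 10,
                    n_samples = 64L, r_absolute_uV = 1, apen = vals)
    electromeR:::new_apen_profile("f1", w, apen_params(), 64L, 64L)
  }
  # V shape: minimum at the 4th window
  d <- detect_dip(mk_profile(c(5, 4, 3, 2, 3, 4, 5)), smooth_k = 1)
  expect_equal(d$dip_index, 4L)
  expect_equal(d$dip_value, 2)
  expect_equal(d$pre_dip_median, 4)
  expect_equal(d$post_dip_median, 4)
  expect_lte(d$dip_value, d$pre_dip_median)
  expect_lte(d$dip_value, d$post_dip_median)

  # monotone decreasing: dip at the last window, no post-dip median
  d2 <- detect_dip(mk_profile(c(7, 6, 5, 4, 3, 2)), smooth_k = 1)
  expect_equal(d2$dip_index, 6L)
  expect_true(is.na(d2$post_dip_median))

  # ties break toward the earliest window
  d3 <- detect_dip(mk_profile(c(3, 1, 2, 1, 3, 4)), smooth_k = 1)
  expect_equal(d3$dip_index, 2L)

  expect_error(detect_dip(mk_profile(c(1, 2, 3)), smooth_k = 5),
               class = "electromeR_too_few_windows")
  expect_error(detect_dip(mk_profile(1:10), smooth_k = 4),
               class = "electromeR_invalid_input")
})

test_that("smoothing makes the dip robust to a single spiked window", {
  vals <- c(5, 5, 5, 0.1, 5, 2, 2, 2, 5, 5)  # isolated outlier at 4
  w <- data.frame(start_s = (0:9) * 10, end_s = (1:10) * 10,
                  n_samples = 64L, r_absolute_uV = 1, apen = vals)
  prof <- electromeR:::new_apen_profile("f1", w, apen_params(), 64L, 64L)
  d <- detect_dip(prof, smooth_k = 5)
  expect_true(d$dip_index %in% 5:8)  # the plateau, not the outlier at 4
})

test_that("dip is localized inside the breaker stage of a synthetic fruit", {
  co <- simulate_cohort(cohort_config(n_fruits = 1, seconds_per_day = 120,
                                      master_seed = 3))
  prof <- profile_cohort(co, window_len_samples = 512)[[1]]
  d <- detect_dip(prof, trajectory = co$trajectories[[1]])
  expect_identical(d$dip_in_stage, "B")
  expect_lt(d$dip_value, d$pre_dip_median)
  expect_lt(d$dip_value, d$post_dip_median)
})

test_that("transition-day summary reproduces forced arithmetic", {
  tr1 <- ripening_trajectory("f1", c("MG", "B"), c(1, 4), c(4, 6))
  s1 <- transition_days_summary(list(tr1))
  expect_equal(s1$from_stage, "MG")
  expect_equal(s1$mean_days, 3)
  expect_equal(s1$sd_days, 0)

  tr2 <- ripening_trajectory("f2", c("MG", "B"), c(1, 3), c(3, 6))
  tr3 <- ripening_trajectory("f3", c("MG", "B"), c(1, 5), c(5, 6))
  s2 <- transition_days_summary(list(tr2, tr3))
  expect_equal(s2$mean_days, 3)   # durations 2 and 4
  expect_equal(s2$sd_days, 1)     # population SD
  expect_equal(s2$n_fruits, 2L)
})

test_that("trajectory validation enforces order and contiguity", {
  expect_error(ripening_trajectory("f", c("B", "MG"), c(1, 3), c(3, 5)),
               class = "electromeR_invalid_trajectory")
  expect_error(ripening_trajectory("f", c("MG", "B"), c(1, 4), c(3, 6)),
               class = "electromeR_invalid_trajectory")
  expect_error(ripening_trajectory("f", "MG", 3, 2),
               class = "electromeR_invalid_trajectory")
  tr <- ripening_trajectory("f", c("MG", "BR", "LR"), c(1, 4, 6), c(4, 6, 9))
  expect_identical(tr$stages$stage, c("MG", "B", "LR"))
  expect_identical(stage_for_day(tr, c(1, 4, 8, 9)),
                   c("MG", "B", "LR", NA))
})
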