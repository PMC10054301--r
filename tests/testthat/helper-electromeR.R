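# Shared fixtures, all generated in code.

# Deterministic chaotic series: logistic map at full chaos.
logistic_series <- function(n = 300, x0 = 0.3) {
  x <- numeric(n)
  x[1] <- x0
  for (k in 2:n) x[k] <- 4 * x[k - 1] * (1 - x[k - 1])
  x
}

# A small desk-scale cohort configuration: default signal and duration
# settings, with short per-day acquisitions so cohort-level tests run fast.
desk_cohort_config <- function(master_seed, n_fruits = 20L,
                               seconds_per_day = 120) {
  cohort_config(n_fruits = n_fruits, seconds_per_day = seconds_per_day,
                master_seed = master_seed)
}

# Windowed feature table of a desk-scale cohort, restricted to two stages,
# split by fruit into train (first 12) and test (last 8).
mg_b_split <- function(master_seed, stages = c("MG", "B"),
                       window = 512L) {
  co <- simulate_cohort(desk_cohort_config(master_seed))
  feats <- cohort_features(co, window_len_samples = window)
  fruits <- sort(unique(feats$fruit_id))
  keep <- feats$stage %in% stages
  list(train = feats[keep & feats$fruit_id %in% fruits[1:12], ],
       test = feats[keep & feats$fruit_id %in% fruits[13:20], ])
}

all_feature_names <- c("apen", "sd_uV", "skewness", "excess_kurtosis",
                       "mean_abs_successive_diff", "lag1_autocorrelation")
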