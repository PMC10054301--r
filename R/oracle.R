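# Brute-force reference implementation of approximate entropy.
#
# A literal transcription of the definition in plain R, kept deliberately
# separate from the fast compiled path so the two can be compared as
# independent routes to the same quantity.

# Match counts computed per template with an explicit pass over all other
# templates; no pruning, no early exit, no shared code with the fast engine.
phi_match_counts_r <- function(x, m, r, metric) {
  E <- embed_vectors(x, m)
  M <- nrow(E)
  counts <- integer(M)
  r2 <- r * r
  for (i in seq_len(M)) {
    if (metric == "chebyshev") {
      ok <- rep(TRUE, M)
      for (k in seq_len(m)) {
        ok <- ok & (abs(E[, k] - E[i, k]) <= r)
      }
    } else {
      s <- numeric(M)
      for (k in seq_len(m)) {
        d <- E[, k] - E[i, k]
        s <- s + d * d
      }
      ok <- s <= r2
    }
    counts[i] <- sum(ok)
  }
  counts
}

#' Brute-force approximate entropy (verification oracle)
#'
#' Computes ApEn by the definition, with an explicit quadratic pass over all
#' template pairs in plain R and no algorithmic shortcuts. Agrees with
#' [apen()] to within 1e-10 and exists so that the fast implementation can be
#' checked against an independent route on every fixture. Guarded to
#' `N <= 2000` because of its quadratic cost.
#'
#' @inheritParams apen
#' @return An `apen_result`, as from [apen()].
#' @export
#' @examples
#' x <- rep(c(0, 1), 50)
#' abs(apen_oracle(x)$value - apen(x)$value) < 1e-10
apen_oracle <- function(series, params = apen_params(), r_absolute = NULL) {
  if (inherits(series, "voltage_series")) series <- series$samples
  x <- as.numeric(series)
  check_finite_numeric(x, "series")
  if (!inherits(params, "apen_params")) {
    stop_electrome("invalid_input", "params must be an apen_params object")
  }
  n <- length(x)
  if (n > 2000L) {
    stop_electrome("oracle_size",
                   sprintf("oracle is O(N^2) and refuses N = %d > 2000", n))
  }
  m <- params$m
  if (n < m + 3L) {
    stop_electrome("series_too_short",
                   sprintf("ApEn needs N >= m + 3: got N = %d, m = %d", n, m))
  }
  if (is.null(r_absolute)) {
    r_absolute <- params$r_factor * sqrt(mean((x - mean(x))^2))
  }
  phi_of <- function(mm) {
    M <- n - mm + 1L
    counts <- phi_match_counts_r(x, mm, r_absolute, params$metric)
    if (!params$self_match) {
      counts <- counts - 1L
      if (any(counts == 0L)) {
        i <- which(counts == 0L)[1L]
        stop_electrome("no_match",
                       sprintf("template %d has no match within r = %g", i,
                               r_absolute))
      }
    }
    mean(log(counts / M))
  }
  p_m <- phi_of(m)
  p_m1 <- phi_of(m + 1L)
  structure(
    list(value = p_m - p_m1, n_samples = n, r_absolute = r_absolute,
         phi_m = p_m, phi_m_plus_1 = p_m1, params = params),
    class = "apen_result"
  )
}
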