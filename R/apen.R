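# Approximate entropy: ApEn(m, r) = phi^m(r) - phi^(m+1)(r).
#
# phi^m(r) is the mean over the M = N - m + 1 template vectors of the natural
# log of the fraction of vectors within tolerance r of each template. With
# self-matches included every fraction is >= 1/M, all logs are finite and
# ApEn >= 0. Low values mean a repetitive, predictable series; high values an
# irregular one.

#' Approximate entropy parameters
#'
#' Bundles the tunables of the ApEn statistic. The defaults — embedding
#' dimension `m` of 2 and tolerance 0.2 times the series standard
#' deviation — are the standard choice for biosignal regularity analysis and
#' the ones used throughout this package's fruit electrome pipeline.
#'
#' @param m Embedding dimension, a positive integer (default 2): the length of
#'   the template vectors formed from consecutive samples.
#' @param r_factor Tolerance as a fraction of the series' population standard
#'   deviation, a positive real (default 0.2).
#' @param metric Distance between template vectors: `"chebyshev"` (max norm,
#'   the classical Pincus formulation, default) or `"euclidean"`. Both treat a
#'   distance exactly equal to `r` as a match.
#' @param self_match Count each template as matching itself (default `TRUE`).
#'   With self-matches every match fraction is positive, so ApEn is finite and
#'   non-negative. With `self_match = FALSE` a template with no other match
#'   makes phi undefined and an error is raised.
#' @return An object of class `apen_params`.
#' @export
#' @examples
#' apen_params()
#' apen_params(m = 3, metric = "euclidean")
apen_params <- function(m = 2L, r_factor = 0.2,
                        metric = c("chebyshev", "euclidean"),
                        self_match = TRUE) {
  metric <- match.arg(metric)
  if (length(m) != 1L || !is.finite(m) || m < 1 || m != as.integer(m)) {
    stop_electrome("invalid_input", "m must be a positive integer")
  }
  if (length(r_factor) != 1L || !is.finite(r_factor) || r_factor <= 0) {
    stop_electrome("invalid_input", "r_factor must be a positive real")
  }
  structure(
    list(m = as.integer(m), r_factor = as.numeric(r_factor),
         metric = metric, self_match = isTRUE(self_match)),
    class = "apen_params"
  )
}

#' @export
print.apen_params <- function(x, ...) {
  cat(sprintf("ApEn parameters: m = %d, r = %g x SD, metric = %s, self-match %s\n",
              x$m, x$r_factor, x$metric, if (x$self_match) "on" else "off"))
  invisible(x)
}

#' Embed a series into overlapping template vectors
#'
#' Forms the `N - m + 1` overlapping vectors of `m` consecutive samples,
#' `v_i = (x_i, ..., x_{i+m-1})`, used as templates by the phi statistic.
#'
#' @param series Numeric vector of length `N >= m + 2`.
#' @param m Embedding dimension.
#' @return A numeric matrix with `N - m + 1` rows and `m` columns; row `i` is
#'   the template starting at sample `i`.
#' @export
#' @examples
#' embed_vectors(c(0, 1, 0, 1, 0, 1), m = 2)
embed_vectors <- function(series, m) {
  x <- as.numeric(series)
  n <- length(x)
  if (length(m) != 1L || !is.finite(m) || m < 1 || m != as.integer(m)) {
    stop_electrome("invalid_input", "m must be a positive integer")
  }
  m <- as.integer(m)
  if (n <= m + 1L) {
    stop_electrome("series_too_short",
                   sprintf("need N >= m + 2 to embed: got N = %d, m = %d", n, m))
  }
  M <- n - m + 1L
  out <- vapply(seq_len(m), function(k) x[k:(k + M - 1L)], numeric(M))
  matrix(out, nrow = M, ncol = m)
}

#' Tolerance from a series' standard deviation
#'
#' The ApEn match tolerance in signal units: `r_factor` times the population
#' (divide-by-N) standard deviation of the series. A constant series has zero
#' standard deviation and yields a zero tolerance; with the inclusive match rule
#' identical vectors still match at distance 0, so ApEn of a constant series
#' is exactly 0 rather than an error.
#'
#' @param series Non-empty numeric vector (micro-volts in this package's
#'   pipeline).
#' @param r_factor Fraction of the standard deviation (default 0.2).
#' @return Absolute tolerance, same units as the series.
#' @export
#' @examples
#' tolerance_from_series(c(0, 2))        # population SD 1 -> 0.2
#' tolerance_from_series(rep(5, 100))    # constant -> 0
tolerance_from_series <- function(series, r_factor = 0.2) {
  check_finite_numeric(series, "series")
  if (length(r_factor) != 1L || !is.finite(r_factor) || r_factor <= 0) {
    stop_electrome("invalid_input", "r_factor must be a positive real")
  }
  r_factor * pop_sd(as.numeric(series))
}

# Shared validation for phi computations; returns the integer match counts.
phi_counts <- function(x, m, r_absolute, metric, self_match, engine) {
  M <- length(x) - m + 1L
  counts <- if (engine == "cpp") {
    .phi_match_counts_cpp(x, m, r_absolute, metric == "chebyshev")
  } else {
    phi_match_counts_r(x, m, r_absolute, metric)
  }
  if (!self_match) {
    counts <- counts - 1L
    if (any(counts == 0L)) {
      i <- which(counts == 0L)[1L]
      stop_electrome("no_match",
                     sprintf(paste0("template %d has no match within r = %g ",
                                    "and self-matches are excluded"),
                             i, r_absolute))
    }
  }
  counts
}

#' The phi statistic of approximate entropy
#'
#' For each template vector `v_i`, `C_i` is the fraction of template vectors
#' within distance `r` of `v_i` (self-match included by default); `phi` is the
#' mean of `ln C_i` over templates. The match rule is inclusive: a pair at
#' distance exactly `r` counts as a match.
#'
#' @param series Numeric vector, length `N >= m + 2`, all values finite.
#' @param m Embedding dimension.
#' @param r_absolute Absolute tolerance (same units as the series), `>= 0`.
#' @param metric `"chebyshev"` or `"euclidean"`.
#' @param self_match Include the self-match (default `TRUE`).
#' @return The phi value (a non-positive real), with the integer per-template
#'   match counts attached as attribute `"counts"`.
#' @export
#' @examples
#' apen_phi(rep(1, 10), m = 2, r_absolute = 0)   # constant series: phi = 0
apen_phi <- function(series, m, r_absolute,
                     metric = c("chebyshev", "euclidean"), self_match = TRUE) {
  metric <- match.arg(metric)
  x <- as.numeric(series)
  check_finite_numeric(x, "series")
  if (length(m) != 1L || !is.finite(m) || m < 1 || m != as.integer(m)) {
    stop_electrome("invalid_input", "m must be a positive integer")
  }
  m <- as.integer(m)
  if (length(x) <= m + 1L) {
    stop_electrome("series_too_short",
                   sprintf("need N >= m + 2: got N = %d, m = %d", length(x), m))
  }
  if (!is.finite(r_absolute) || r_absolute < 0) {
    stop_electrome("invalid_input", "r_absolute must be a non-negative real")
  }
  M <- length(x) - m + 1L
  counts <- phi_counts(x, m, r_absolute, metric, self_match, engine = "cpp")
  phi <- mean(log(counts / M))
  attr(phi, "counts") <- as.integer(counts)
  phi
}

#' Approximate entropy of a voltage time series
#'
#' Computes `ApEn(m, r) = phi^m(r) - phi^(m+1)(r)` with the tolerance `r`
#' fixed once from the standard deviation of the full input series (so a
#' windowed caller gets a per-window tolerance). Deterministic for a fixed
#' input. Low ApEn means repetitive, predictable dynamics; high ApEn means
#' irregular, complex dynamics.
#'
#' @param series Numeric vector (a [voltage_series] is accepted and its
#'   samples used), length `N >= m + 3`, all values finite. ApEn estimates are
#'   biased at very small `N`; a warning is emitted below `N = 50`.
#' @param params An [apen_params] object.
#' @param r_absolute Optional tolerance override in signal units. By default
#'   the tolerance is `params$r_factor` times the population SD of `series`;
#'   pass a value here to use a global tolerance across several windows.
#' @return An object of class `apen_result`: a list with elements `value`
#'   (ApEn in nats), `n_samples`, `r_absolute`, `phi_m`, `phi_m_plus_1`, and
#'   the `params` used.
#' @seealso [apen_oracle()] for the brute-force reference implementation,
#'   [windowed_apen()] for sliding-window profiles.
#' @export
#' @examples
#' apen(rep(3.2, 100))$value                    # constant series: exactly 0
#' set.seed(1)
#' apen(runif(300))$value                       # irregular: large
#' apen(rep(c(0, 1), 150))$value                # period 2: near 0
apen <- function(series, params = apen_params(), r_absolute = NULL) {
  if (inherits(series, "voltage_series")) series <- series$samples
  x <- as.numeric(series)
  check_finite_numeric(x, "series")
  if (!inherits(params, "apen_params")) {
    stop_electrome("invalid_input", "params must be an apen_params object")
  }
  m <- params$m
  n <- length(x)
  if (n < m + 3L) {
    stop_electrome("series_too_short",
                   sprintf("ApEn needs N >= m + 3: got N = %d, m = %d", n, m))
  }
  if (n < 50L) {
    warning(sprintf("ApEn is biased at small N (N = %d < 50)", n),
            call. = FALSE)
  }
  if (is.null(r_absolute)) {
    r_absolute <- tolerance_from_series(x, params$r_factor)
  }
  if (!is.finite(r_absolute) || r_absolute < 0) {
    stop_electrome("invalid_input", "r_absolute must be a non-negative real")
  }
  p_m <- apen_phi(x, m, r_absolute, params$metric, params$self_match)
  p_m1 <- apen_phi(x, m + 1L, r_absolute, params$metric, params$self_match)
  structure(
    list(value = as.numeric(p_m) - as.numeric(p_m1),
         n_samples = n,
         r_absolute = r_absolute,
         phi_m = as.numeric(p_m),
         phi_m_plus_1 = as.numeric(p_m1),
         params = params),
    class = "apen_result"
  )
}

#' @export
print.apen_result <- function(x, ...) {
  cat(sprintf("ApEn(m = %d, r = %g x SD) = %.6f nats  [N = %d, r = %g]\n",
              x$params$m, x$params$r_factor, x$value, x$n_samples,
              x$r_absolute))
  invisible(x)
}

#' @export
as.numeric.apen_result <- function(x, ...) x$value
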