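# Shared internal helpers: classed errors, seeding, moments.

# Signal a classed condition so callers can distinguish failure modes.
stop_electrome <- function(class, message) {
  stop(structure(
    class = c(paste0("electromeR_", class), "electromeR_error",
              "error", "condition"),
    list(message = message, call = NULL)
  ))
}

# Evaluate `expr` under a fixed RNG seed, restoring prior RNG state afterwards.
# All package randomness flows through this helper so that no call leaks
# global RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% 2147483647))
  }
  expr
}

#' Derive a deterministic child seed
#'
#' Pure integer function of a master seed and any number of stream indices
#' (for example fruit index and day index), so that every simulated fruit and
#' acquisition has its own reproducible random stream with no shared state.
#'
#' @param ... Integers: master seed followed by stream indices.
#' @return A single integer seed in `[0, 2147483562]`.
#' @export
#' @examples
#' child_seed(42, 3, 1)
child_seed <- function(...) {
  ids <- as.numeric(c(...))
  if (length(ids) == 0L || anyNA(ids)) {
    stop_electrome("invalid_input", "child_seed() needs at least one finite id")
  }
  s <- 0
  # Multiplicative-congruential style mixing kept inside double precision:
  # s < 2147483563 so s * 69069 < 2^53; ids are folded in one at a time.
  for (v in ids) {
    s <- (s * 69069 + (abs(v) + 1) * 40503 + 97) %% 2147483563
  }
  as.integer(s)
}

# Population (divide-by-N) standard deviation.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Population central moments standardized: skewness and excess kurtosis.
pop_skewness <- function(x) {
  s <- pop_sd(x)
  if (s == 0) return(0)
  mean((x - mean(x))^3) / s^3
}

pop_excess_kurtosis <- function(x) {
  s <- pop_sd(x)
  if (s == 0) return(0)
  mean((x - mean(x))^4) / s^4 - 3
}

check_finite_numeric <- function(x, what) {
  if (!is.numeric(x)) {
    stop_electrome("invalid_input", sprintf("%s must be numeric", what))
  }
  if (length(x) == 0L) {
    stop_electrome("invalid_input", sprintf("%s is empty", what))
  }
  if (!all(is.finite(x))) {
    idx <- which(!is.finite(x))[1L]
    stop_electrome("nonfinite_input",
                   sprintf("%s contains a non-finite value at position %d",
                           what, idx))
  }
  invisible(x)
}
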