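# Ripening trajectories: the stage label of one fruit as a step function of
# experiment day, with derived transition days.

#' A fruit's ripening trajectory
#'
#' A step function of experiment day: an ordered list of contiguous,
#' non-overlapping stage intervals `[start_day, end_day)` (1-based days),
#' whose labels respect the canonical ripening order
#' `IMG < MG < B < OR < LR < R`.
#'
#' @param fruit_id Fruit identifier.
#' @param stage Character vector of stage labels (`"BR"` accepted for `"B"`).
#' @param start_day,end_day Numeric vectors: half-open day intervals, one per
#'   stage, contiguous and strictly increasing.
#' @return An object of class `ripening_trajectory` with elements `fruit_id`,
#'   `stages` (a data frame `stage, start_day, end_day`) and
#'   `transition_days` (the interior interval boundaries).
#' @export
#' @examples
#' ripening_trajectory("fruit01", stage = c("MG", "B", "LR"),
#'                     start_day = c(1, 5, 7), end_day = c(5, 7, 9))
ripening_trajectory <- function(fruit_id, stage, start_day, end_day) {
  stage <- normalize_stage(stage)
  if (length(stage) == 0L) {
    stop_electrome("invalid_input", "trajectory needs at least one stage")
  }
  if (length(start_day) != length(stage) || length(end_day) != length(stage)) {
    stop_electrome("invalid_input",
                   "stage, start_day and end_day must have equal length")
  }
  start_day <- as.numeric(start_day)
  end_day <- as.numeric(end_day)
  if (any(!is.finite(start_day)) || any(!is.finite(end_day))) {
    stop_electrome("invalid_input", "trajectory days must be finite")
  }
  if (any(end_day <= start_day)) {
    i <- which(end_day <= start_day)[1L]
    stop_electrome("invalid_trajectory",
                   sprintf("stage %s has end_day <= start_day (%g <= %g)",
                           stage[i], end_day[i], start_day[i]))
  }
  if (length(stage) > 1L) {
    if (any(start_day[-1L] != end_day[-length(end_day)])) {
      stop_electrome("invalid_trajectory",
                     "stage intervals must be contiguous and non-overlapping")
    }
    ord <- match(stage, stage_levels())
    if (any(diff(ord) <= 0)) {
      stop_electrome("invalid_trajectory",
                     sprintf("stage order violates the ripening sequence %s",
                             paste(stage_levels(), collapse = " < ")))
    }
  }
  structure(
    list(fruit_id = as.character(fruit_id),
         stages = data.frame(stage = stage, start_day = start_day,
                             end_day = end_day, stringsAsFactors = FALSE),
         transition_days = if (length(stage) > 1L) end_day[-length(end_day)]
                           else numeric(0)),
    class = "ripening_trajectory"
  )
}

#' @export
print.ripening_trajectory <- function(x, ...) {
  cat(sprintf("<ripening_trajectory> %s: %s\n", x$fruit_id,
              paste(sprintf("%s [%g, %g)", x$stages$stage, x$stages$start_day,
                            x$stages$end_day), collapse = " -> ")))
  invisible(x)
}

#' Stage covering a given experiment day
#'
#' @param trajectory A [ripening_trajectory].
#' @param day Numeric day(s); a day `d` falls in the interval with
#'   `start_day <= d < end_day`.
#' @return Character vector of stage labels, `NA` where the day is outside
#'   every interval.
#' @export
stage_for_day <- function(trajectory, day) {
  if (!inherits(trajectory, "ripening_trajectory")) {
    stop_electrome("invalid_input", "trajectory must be a ripening_trajectory")
  }
  s <- trajectory$stages
  vapply(as.numeric(day), function(d) {
    hit <- which(s$start_day <= d & d < s$end_day)
    if (length(hit) == 1L) s$stage[hit] else NA_character_
  }, character(1))
}

#' Summary of days spent in each stage before transition
#'
#' For every consecutive stage pair observed across the trajectories (for
#' example `MG -> B`), reports the mean and population standard deviation of
#' the days spent in the earlier stage, across fruits. This reproduces the
#' kind of between-stage timing summary reported for ripening cohorts.
#'
#' @param trajectories A list of [ripening_trajectory] objects (or one).
#' @return A data frame with columns `from_stage, to_stage, mean_days,
#'   sd_days, n_fruits`.
#' @export
#' @examples
#' tr <- ripening_trajectory("f1", c("MG", "B"), c(1, 4), c(4, 6))
#' transition_days_summary(list(tr))
transition_days_summary <- function(trajectories) {
  if (inherits(trajectories, "ripening_trajectory")) {
    trajectories <- list(trajectories)
  }
  if (length(trajectories) == 0L) {
    stop_electrome("invalid_input", "need at least one trajectory")
  }
  rows <- do.call(rbind, lapply(trajectories, function(tr) {
    s <- tr$stages
    if (nrow(s) < 2L) return(NULL)
    k <- seq_len(nrow(s) - 1L)
    data.frame(from_stage = s$stage[k], to_stage = s$stage[k + 1L],
               days = s$end_day[k] - s$start_day[k],
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    return(data.frame(from_stage = character(0), to_stage = character(0),
                      mean_days = numeric(0), sd_days = numeric(0),
                      n_fruits = integer(0)))
  }
  key <- paste(rows$from_stage, rows$to_stage, sep = "->")
  out <- do.call(rbind, lapply(split(rows, key), function(g) {
    data.frame(from_stage = g$from_stage[1L], to_stage = g$to_stage[1L],
               mean_days = mean(g$days),
               sd_days = pop_sd(g$days),
               n_fruits = nrow(g), stringsAsFactors = FALSE)
  }))
  out <- out[order(match(out$from_stage, stage_levels())), , drop = FALSE]
  rownames(out) <- NULL
  out
}
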