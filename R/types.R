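#' Sleep states used throughout the package
#'
#' Ordered set of sleep-stage labels produced by wrist actigraphy staging:
#' wake, light, deep and REM sleep.
#' @export
SLEEP_STATES <- c("wake", "light", "deep", "rem")

#' Construct a glucose trace
#'
#' A glucose trace holds one participant's timestamped interstitial glucose
#' series in mg/dl, normally on a 15-minute grid after resampling. Timestamps
#' must be strictly increasing and glucose values positive.
#'
#' @param participant_id Identifier string.
#' @param time `POSIXct` vector of sample times (timezone-naive local time,
#'   stored as UTC).
#' @param glucose Numeric vector of glucose values in mg/dl; `NA` marks a
#'   missing grid slot.
#' @param grid_minutes Nominal sampling cadence in minutes (default 15).
#' @return An object of class `glucose_trace`.
#' @export
glucose_trace <- function(participant_id, time, glucose, grid_minutes = 15) {
  stopifnot(length(time) == length(glucose))
  if (!inherits(time, "POSIXct")) stop("`time` must be POSIXct")
  obs <- !is.na(glucose)
  if (any(glucose[obs] <= 0)) stop("glucose values must be positive")
  if (length(time) > 1 && any(diff(as.numeric(time)) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  structure(
    list(
      participant_id = as.character(participant_id),
      samples = data.frame(time = time, glucose = as.numeric(glucose)),
      grid_minutes = grid_minutes
    ),
    class = "glucose_trace"
  )
}

#' @export
print.glucose_trace <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf(
    "<glucose_trace> %s: %d samples (%s .. %s), %d-min grid\n",
    x$participant_id, n,
    format(x$samples$time[1]), format(x$samples$time[n]), x$grid_minutes
  ))
  invisible(x)
}

#' Construct a hypnogram
#'
#' A hypnogram is one night's sleep-state sequence: an ordered set of
#' contiguous, non-overlapping epochs, each a maximal run of one state with a
#' start time and duration. The night is attributed to the calendar date on
#' which it ends (the waking morning), following the sleep-log convention.
#'
#' @param participant_id Identifier string.
#' @param night_date `Date` of the morning the night ends.
#' @param state Character vector of epoch states, each one of
#'   [SLEEP_STATES].
#' @param start `POSIXct` vector of epoch start times.
#' @param duration_min Numeric vector of epoch durations in minutes (> 0).
#' @return An object of class `hypnogram` with fields `epochs` (data frame),
#'   `bed_start` and `bed_end`.
#' @export
hypnogram <- function(participant_id, night_date, state, start, duration_min) {
  stopifnot(length(state) == length(start), length(start) == length(duration_min))
  if (length(state) < 1) stop("a hypnogram needs at least one epoch")
  bad <- setdiff(unique(state), SLEEP_STATES)
  if (length(bad)) stop("unknown sleep state label: ", paste(bad, collapse = ", "))
  if (any(duration_min <= 0)) stop("epoch durations must be positive")
  ends <- as.numeric(start) + duration_min * 60
  if (length(start) > 1 &&
      any(abs(as.numeric(start[-1]) - ends[-length(ends)]) > 1e-6)) {
    stop("epochs must be contiguous and non-overlapping")
  }
  structure(
    list(
      participant_id = as.character(participant_id),
      night_date = as.Date(night_date),
      epochs = data.frame(
        state = state, start = start, duration_min = as.numeric(duration_min)
      ),
      bed_start = start[1],
      bed_end = start[length(start)] + duration_min[length(duration_min)] * 60
    ),
    class = "hypnogram"
  )
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf(
    "<hypnogram> %s night of %s: %d epochs, in bed %s .. %s\n",
    x$participant_id, format(x$night_date), nrow(x$epochs),
    format(x$bed_start, "%H:%M"), format(x$bed_end, "%H:%M")
  ))
  invisible(x)
}

#' Expand a hypnogram into fixed-length slots
#'
#' Returns the per-slot state sequence obtained by cutting the night into
#' consecutive slots of `slot_minutes`, assigning each slot the state that
#' occupies most of it (ties go to the state entered earliest in the slot).
#'
#' @param night A [hypnogram()].
#' @param slot_minutes Slot length in minutes (default 15).
#' @return Character vector of states, one per slot.
#' @export
hypnogram_slots <- function(night, slot_minutes = 15) {
  e <- night$epochs
  t0 <- as.numeric(night$bed_start)
  total <- as.numeric(night$bed_end) - t0
  n_slot <- ceiling(total / (slot_minutes * 60) - 1e-9)
  # minute-resolution expansion, then majority vote per slot
  mins <- rep(e$state, times = round(e$duration_min))
  out <- character(n_slot)
  for (s in seq_len(n_slot)) {
    idx <- ((s - 1) * slot_minutes + 1):min(s * slot_minutes, length(mins))
    slot_states <- mins[idx]
    counts <- table(factor(slot_states, levels = SLEEP_STATES))
    winners <- names(counts)[counts == max(counts)]
    out[s] <- if (length(winners) == 1) winners else
      slot_states[match(TRUE, slot_states %in% winners)]
  }
  out
}

# Merge a per-slot state sequence back into maximal same-state epochs.
slots_to_epochs <- function(states, start, slot_minutes = 15) {
  r <- rle(states)
  n <- length(r$lengths)
  starts <- start + c(0, cumsum(r$lengths[-n])) * slot_minutes * 60
  data.frame(
    state = r$values, start = starts,
    duration_min = r$lengths * slot_minutes
  )
}
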