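#' Read a flash-CGM CSV export
#'
#' Parses the meter-export dialect: a header row with columns `Device`,
#' `Serial Number`, `Device Timestamp` (`DD-MM-YYYY HH:MM`), `Record Type`
#' and `Historic Glucose mg/dL`. Only historic rows (`Record Type == 0`) are
#' used. Rows are sorted by time; duplicate timestamps collapse to the first
#' occurrence; malformed rows (unparseable time or glucose) are collected in
#' a rejects report attached as attribute `"rejects"` rather than aborting
#' the read.
#'
#' @param path Path to the CSV file.
#' @param participant_id Optional identifier; defaults to the file's
#'   `Serial Number` column.
#' @return A [glucose_trace()] with attribute `"rejects"` (data frame of
#'   rejected rows and reasons, possibly empty).
#' @export
read_cgm_csv <- function(path, participant_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0) stop("empty CGM file: ", path)
  needed <- c("Device Timestamp", "Record Type", "Historic Glucose mg/dL")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("CGM file lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  raw <- raw[raw[["Record Type"]] == "0", , drop = FALSE]
  if (nrow(raw) == 0) stop("no historic-glucose rows in: ", path)
  time <- as.POSIXct(raw[["Device Timestamp"]],
                     format = "%d-%m-%Y %H:%M", tz = "UTC")
  glucose <- suppressWarnings(as.numeric(raw[["Historic Glucose mg/dL"]]))
  bad <- is.na(time) | is.na(glucose) | glucose <= 0
  rejects <- data.frame(
    row = which(bad),
    timestamp = raw[["Device Timestamp"]][bad],
    value = raw[["Historic Glucose mg/dL"]][bad],
    reason = ifelse(is.na(time[bad]), "bad_timestamp", "bad_glucose")
  )
  time <- time[!bad]; glucose <- glucose[!bad]
  if (!length(time)) stop("no valid rows in: ", path)
  ord <- order(time)
  time <- time[ord]; glucose <- glucose[ord]
  keep <- !duplicated(time)
  pid <- participant_id %||% raw[["Serial Number"]][1] %||% "unknown"
  tr <- glucose_trace(pid, time[keep], glucose[keep])
  attr(tr, "rejects") <- rejects
  tr
}

#' Read a wrist-tracker sleep-log JSON
#'
#' Parses the sleep-log dialect: a JSON array of logs, each with
#' `dateOfSleep`, `isMainSleep` and a `levels.data` array of
#' `{dateTime, level, seconds}` stage blocks. One [hypnogram()] is returned
#' per main-sleep record; naps (`isMainSleep == false`) are skipped here and
#' nocturnal-window filtering is applied later by [filter_days()]. Stage
#' labels must be one of [SLEEP_STATES] (`"awake"` is accepted as `"wake"`);
#' any other label is an error naming the label.
#'
#' @param path Path to the JSON file.
#' @param participant_id Identifier; defaults to the file name stem (with a
#'   trailing `_sleep` stripped).
#' @return List of [hypnogram()] objects.
#' @export
read_sleep_json <- function(path, participant_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pid <- participant_id %||%
    sub("_sleep$", "", tools::file_path_sans_ext(basename(path)))
  logs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  main <- Filter(function(l) isTRUE(l$isMainSleep), logs)
  lapply(main, function(l) {
    d <- l$levels$data
    state <- vapply(d, function(x) as.character(x$level), "")
    state[state == "awake"] <- "wake"
    bad <- setdiff(unique(state), SLEEP_STATES)
    if (length(bad)) {
      stop("unknown sleep stage label: ", paste(bad, collapse = ", "))
    }
    start <- as.POSIXct(
      vapply(d, function(x) as.character(x$dateTime), ""),
      format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC"
    )
    dur <- vapply(d, function(x) as.numeric(x$seconds), 0) / 60
    hypnogram(pid, as.Date(l$dateOfSleep), state, start, dur)
  })
}

# Resample a trace to a fixed grid: nearest snapped sample within half the
# grid spacing; otherwise the slot is a gap (NA).
resample_to_grid <- function(time, glucose, grid) {
  out <- rep(NA_real_, length(grid))
  if (!length(time)) return(out)
  idx <- findInterval(as.numeric(grid), as.numeric(time))
  for (i in seq_along(grid)) {
    lo <- idx[i]; cand <- c(lo, lo + 1)
    cand <- cand[cand >= 1 & cand <= length(time)]
    if (!length(cand)) next
    d <- abs(as.numeric(time[cand]) - as.numeric(grid[i]))
    j <- cand[which.min(d)]  # tie -> earlier sample
    if (min(d) <= 7.5 * 60) out[i] <- glucose[j]
  }
  out
}

#' Synchronize one night's sleep with its day's glucose
#'
#' Applies the two-stage synchronization used when merging the device
#' streams: every timestamp is snapped to the nearest multiple of 5 minutes
#' (2.5-minute ties round up), then sleep epoch durations are summed into
#' 15-minute bins and the glucose series is resampled onto the 15-minute
#' day grid (up to 96 samples covering the calendar day the night ends on;
#' grid slots with no snapped sample within 7.5 minutes are marked missing).
#'
#' @param glucose A [glucose_trace()] covering (at least part of) the night
#'   and following day.
#' @param night A [hypnogram()].
#' @param grid_minutes Day-grid cadence (default 15).
#' @return A `day_record`: list with `participant_id`, `night` (snapped
#'   hypnogram), `night_bins` (per-15-min stage-minute table and majority
#'   state), `day_glucose` (96-slot grid with `NA` gaps), `night_glucose`
#'   (samples within the bed window), `valid`, `reason`.
#' @export
synchronize <- function(glucose, night, grid_minutes = 15) {
  stopifnot(inherits(glucose, "glucose_trace"), inherits(night, "hypnogram"))
  g_time <- snap_time(glucose$samples$time, 300)
  keep <- !duplicated(g_time)
  g_time <- g_time[keep]
  g_val <- glucose$samples$glucose[keep]

  ep <- night$epochs
  ep$start <- snap_time(ep$start, 300)
  ep$duration_min <- round(ep$duration_min / 5) * 5
  ep <- ep[ep$duration_min > 0, , drop = FALSE]
  bed_start <- ep$start[1]
  # re-anchor starts so the snapped epochs stay contiguous
  ep$start <- bed_start + c(0, cumsum(ep$duration_min[-nrow(ep)])) * 60
  snapped <- hypnogram(night$participant_id, night$night_date,
                       ep$state, ep$start, ep$duration_min)

  bin_start <- snap_time(bed_start, grid_minutes * 60)
  if (bin_start > bed_start) bin_start <- bin_start - grid_minutes * 60
  n_bins <- ceiling(as.numeric(difftime(snapped$bed_end, bin_start,
                                        units = "mins")) / grid_minutes)
  mins <- rep(ep$state, times = round(ep$duration_min))
  offset <- as.numeric(difftime(bed_start, bin_start, units = "mins"))
  slot_of <- floor((offset + seq_along(mins) - 1) / grid_minutes) + 1
  night_bins <- data.frame(slot_start = bin_start +
                             (seq_len(n_bins) - 1) * grid_minutes * 60)
  for (s in SLEEP_STATES) {
    night_bins[[paste0(s, "_min")]] <-
      vapply(seq_len(n_bins),
             function(b) sum(mins[slot_of == b] == s), 0)
  }
  cnt <- as.matrix(night_bins[, paste0(SLEEP_STATES, "_min")])
  night_bins$state <- SLEEP_STATES[max.col(cnt, ties.method = "first")]

  day0 <- local_time(paste(night$night_date, "00:00:00"))
  grid <- seq(day0, by = grid_minutes * 60,
              length.out = 24 * 60 / grid_minutes)
  day_vals <- resample_to_grid(g_time, g_val, grid)

  in_bed <- g_time >= snapped$bed_start & g_time <= snapped$bed_end
  overlap <- any(in_bed) || any(!is.na(day_vals))
  night_glucose <- data.frame(time = g_time[in_bed], glucose = g_val[in_bed])

  structure(
    list(
      participant_id = night$participant_id,
      night = snapped,
      night_bins = night_bins,
      day_glucose = data.frame(time = grid, glucose = day_vals),
      night_glucose = night_glucose,
      valid = overlap,
      reason = if (overlap) NA_character_ else "no_overlap"
    ),
    class = "day_record"
  )
}

max_gap_minutes <- function(day_glucose, grid_minutes = 15) {
  obs <- which(!is.na(day_glucose$glucose))
  n <- nrow(day_glucose)
  if (!length(obs)) return(Inf)
  # gaps between observed neighbours, plus lead-in/tail-out to day edges
  internal <- if (length(obs) > 1) max(diff(obs)) * grid_minutes else 0
  lead <- (obs[1] - 1) * grid_minutes
  tail <- (n - obs[length(obs)]) * grid_minutes
  max(internal, lead, tail)
}

#' Filter synchronized day records
#'
#' Applies the day-level exclusion rules: a day is discarded when its glucose
#' series has a gap strictly greater than `max_gap_min` minutes (gaps of
#' exactly 90 minutes are kept), or when the main sleep's midpoint falls
#' outside the nocturnal window (an automated proxy for removing naps and
#' mislabelled daytime sleeps), or when synchronization found no temporal
#' overlap. Nothing is lost: kept + discarded = input, and every discard
#' carries a reason.
#'
#' @param records List of `day_record`s from [synchronize()].
#' @param max_gap_min Maximum tolerated glucose gap, minutes (default 90).
#' @param night_window Numeric `c(start_hour, end_hour)` for the allowed
#'   sleep-midpoint clock window, wrapping midnight (default 20:00-12:00).
#' @return List with `kept` (day records) and `discarded` (data frame of
#'   participant_id, night_date, reason).
#' @export
filter_days <- function(records, max_gap_min = 90,
                        night_window = c(20, 12)) {
  kept <- list()
  disc <- list()
  for (r in records) {
    reason <- NA_character_
    if (!isTRUE(r$valid)) {
      reason <- r$reason %||% "invalid"
    } else if (max_gap_minutes(r$day_glucose) > max_gap_min) {
      reason <- "glucose_gap"
    } else {
      mid <- r$night$bed_start +
        as.numeric(difftime(r$night$bed_end, r$night$bed_start,
                            units = "secs")) / 2
      h <- minutes_of_day(mid) / 60
      inside <- if (night_window[1] > night_window[2]) {
        h >= night_window[1] | h <= night_window[2]
      } else {
        h >= night_window[1] & h <= night_window[2]
      }
      if (!inside) reason <- "not_nocturnal"
    }
    if (is.na(reason)) {
      kept[[length(kept) + 1]] <- r
    } else {
      disc[[length(disc) + 1]] <- data.frame(
        participant_id = r$participant_id,
        night_date = r$night$night_date,
        reason = reason
      )
    }
  }
  list(
    kept = kept,
    discarded = if (length(disc)) do.call(rbind, disc) else
      data.frame(participant_id = character(), night_date = as.Date(character()),
                 reason = character())
  )
}
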