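#' Per-minute linear interpolation of a glucose trace
#'
#' The Rosendaal-style preprocessing behind every time-in-range figure:
#' assume linear progression between consecutive readings and evaluate the
#' series at every integer minute between the first and last sample. Range
#' accounting, episode counting and MAGE then work on this minute series.
#'
#' @param trace A [glucose_trace()], or a data frame with `time` (`POSIXct`)
#'   and `glucose` columns. Missing samples are dropped first; at least two
#'   observed samples are required.
#' @return Data frame with one row per minute: `time`, `glucose`.
#' @export
interpolate_minutes <- function(trace) {
  s <- if (inherits(trace, "glucose_trace")) trace$samples else trace
  s <- s[!is.na(s$glucose), , drop = FALSE]
  if (nrow(s) < 2) stop("need at least two observed samples to interpolate")
  t0 <- s$time[1]
  tn <- s$time[nrow(s)]
  grid <- seq(t0, tn, by = 60)
  g <- stats::approx(as.numeric(s$time), s$glucose,
                     xout = as.numeric(grid))$y
  data.frame(time = grid, glucose = g)
}

#' Time in glycemic ranges
#'
#' Percentage of minutes spent in each of the five standard bands:
#' level 2 hypoglycemia (< 55), level 1 hypoglycemia (55 to < 70), target
#' range (70-180 inclusive), level 1 hyperglycemia (> 180 to 250) and
#' level 2 hyperglycemia (> 250 mg/dl). The bands partition the glucose axis,
#' so the five percentages sum to 100.
#'
#' @param glucose Numeric vector of per-minute glucose values (mg/dl), e.g.
#'   the `glucose` column of [interpolate_minutes()].
#' @return Named numeric vector: `tir`, `t_hypo_l1`, `t_hypo_l2`,
#'   `t_hyper_l1`, `t_hyper_l2` (percent).
#' @export
time_in_ranges <- function(glucose) {
  g <- glucose[!is.na(glucose)]
  if (!length(g)) stop("empty glucose series")
  n <- length(g)
  c(
    tir        = 100 * sum(g >= 70 & g <= 180) / n,
    t_hypo_l1  = 100 * sum(g >= 55 & g < 70) / n,
    t_hypo_l2  = 100 * sum(g < 55) / n,
    t_hyper_l1 = 100 * sum(g > 180 & g <= 250) / n,
    t_hyper_l2 = 100 * sum(g > 250) / n
  )
}

#' Mean, SD and coefficient of variation of a glucose series
#'
#' @param glucose Numeric vector of glucose values (mg/dl).
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return Named vector `mean`, `sd`, `cv` (cv = 100 * sd / mean).
#' @export
basic_stats <- function(glucose, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  g <- glucose[!is.na(glucose)]
  if (!length(g)) stop("empty glucose series")
  m <- mean(g)
  s <- if (length(g) < 2) 0 else stats::sd(g)
  if (sd_type == "population") s <- s * sqrt((length(g) - 1) / length(g))
  c(mean = m, sd = s, cv = 100 * s / m)
}

#' Count glycemic episodes of minimum duration
#'
#' An episode is a maximal contiguous run of minutes satisfying `predicate`
#' lasting at least `min_duration` minutes. Two qualifying runs separated by
#' as little as one in-range minute count separately.
#'
#' @param glucose Numeric vector of per-minute glucose values.
#' @param predicate Function mapping glucose to logical, e.g.
#'   `function(g) g < 70` for hypoglycemia or `function(g) g > 180` for
#'   hyperglycemia.
#' @param min_duration Minimum run length in minutes (default 15).
#' @return Integer count of episodes.
#' @export
count_episodes <- function(glucose, predicate, min_duration = 15) {
  g <- glucose[!is.na(glucose)]
  if (!length(g)) return(0L)
  r <- rle(as.logical(predicate(g)))
  sum(r$values & r$lengths >= min_duration)
}

# Indices of turning points (local extrema) of a numeric series, after
# collapsing plateaus. Returns indices into the original series including
# both endpoints.
turning_points <- function(x) {
  keep <- c(TRUE, diff(x) != 0)
  xi <- which(keep)
  xv <- x[keep]
  if (length(xv) < 3) return(c(1L, length(x)))
  d <- sign(diff(xv))
  turn <- which(d[-1] != d[-length(d)]) + 1
  unique(c(1L, xi[turn], length(x)))
}

#' Mean amplitude of glycemic excursions (MAGE)
#'
#' Classic 1-SD excursion rule: the minute series is lightly smoothed with a
#' 3-point moving average, its turning points (alternating peaks and nadirs)
#' are located, and MAGE is the mean absolute peak-to-nadir amplitude over
#' the excursions exceeding one standard deviation of the day's (unsmoothed)
#' glucose. Returns `NA` when no excursion qualifies (e.g. a constant day).
#'
#' @param glucose Numeric vector of per-minute glucose values.
#' @param smooth_window Moving-average window in minutes (default 3).
#' @return MAGE in mg/dl, or `NA_real_` when undefined.
#' @export
mage <- function(glucose, smooth_window = 3) {
  g <- glucose[!is.na(glucose)]
  if (length(g) < 3) return(NA_real_)
  k <- smooth_window
  sm <- as.numeric(stats::filter(g, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- g[is.na(sm)]  # keep the ends unsmoothed
  tp <- turning_points(sm)
  if (length(tp) < 2) return(NA_real_)
  amps <- abs(diff(sm[tp]))
  sd_day <- stats::sd(g)
  # the 1e-9 guard keeps float noise from the moving average from counting
  # as an excursion on a flat day (sd 0)
  qual <- amps > sd_day + 1e-9
  if (!any(qual)) return(NA_real_)
  mean(amps[qual])
}

#' Mean daily glucose difference (MDGD / MODD)
#'
#' Mean absolute difference between glucose values at the same clock time on
#' two consecutive days. Pass per-minute series (data frames from
#' [interpolate_minutes()]); minutes present on both days are matched by
#' minute-of-day.
#'
#' @param day1,day2 Data frames with `time` and `glucose` columns.
#' @return MDGD in mg/dl.
#' @export
mdgd <- function(day1, day2) {
  k1 <- round(minutes_of_day(day1$time))
  k2 <- round(minutes_of_day(day2$time))
  common <- intersect(k1, k2)
  if (!length(common)) stop("days share no clock times")
  g1 <- day1$glucose[match(common, k1)]
  g2 <- day2$glucose[match(common, k2)]
  ok <- !is.na(g1) & !is.na(g2)
  if (!any(ok)) stop("days share no observed clock times")
  mean(abs(g2[ok] - g1[ok]))
}

#' Multi-day MDGD
#'
#' Mean of [mdgd()] over consecutive day pairs.
#'
#' @param days List of per-minute series (data frames), in calendar order.
#' @return Mean MDGD in mg/dl, or `NA_real_` with fewer than two days.
#' @export
mdgd_multi <- function(days) {
  if (length(days) < 2) return(NA_real_)
  mean(vapply(seq_len(length(days) - 1),
              function(i) mdgd(days[[i]], days[[i + 1]]), 0))
}

#' Summarize one day's (or night's) glycemia
#'
#' Computes every per-day glycemic variable from a synchronized day record:
#' mean/SD/CV, the five range percentages, hypo-/hyperglycemia episode counts
#' (>= 15 min below 70 / above 180 mg/dl on the minute series), MAGE, and --
#' when the previous day's record is supplied -- MDGD against it.
#'
#' @param record A `day_record` from [synchronize()].
#' @param window `"night"` (bed window, default) or `"day"` (the 96-slot
#'   calendar day).
#' @param prev_record Optional preceding `day_record` for MDGD.
#' @return One-row data frame (class `day_glycemia_summary` fields).
#' @export
summarize_day <- function(record, window = c("night", "day"),
                          prev_record = NULL) {
  window <- match.arg(window)
  if (!isTRUE(record$valid)) stop("cannot summarize an invalid day record")
  pick <- function(r) if (window == "night") r$night_glucose else r$day_glucose
  minutes <- interpolate_minutes(pick(record))
  st <- basic_stats(minutes$glucose)
  rng <- time_in_ranges(minutes$glucose)
  md <- NA_real_
  if (!is.null(prev_record)) {
    md <- mdgd(interpolate_minutes(pick(prev_record)), minutes)
  }
  out <- data.frame(
    participant_id = record$participant_id,
    night_date = record$night$night_date,
    window = window,
    mean_glucose = st[["mean"]], sd = st[["sd"]], cv = st[["cv"]],
    tir = rng[["tir"]],
    t_hypo_l1 = rng[["t_hypo_l1"]], t_hypo_l2 = rng[["t_hypo_l2"]],
    t_hyper_l1 = rng[["t_hyper_l1"]], t_hyper_l2 = rng[["t_hyper_l2"]],
    n_hypo_episodes = count_episodes(minutes$glucose, function(g) g < 70),
    n_hyper_episodes = count_episodes(minutes$glucose, function(g) g > 180),
    mage = mage(minutes$glucose),
    mdgd = md
  )
  out
}

#' Aggregate per-day glycemia to participant and cohort level
#'
#' Per participant: number of days and mean +/- SD of each glycemic variable
#' over that participant's days, with `t_hypo` and `t_hyper` the summed
#' level-1 + level-2 percentages. The overall row (via [cohort_overall()])
#' sums the night counts and takes the unweighted mean of every other column
#' across participants.
#'
#' @param day_summaries Data frame of [summarize_day()] rows.
#' @return List with `participants` (one row each) and `overall` (one row).
#' @export
aggregate_glycemia <- function(day_summaries) {
  d <- day_summaries
  d$t_hypo <- d$t_hypo_l1 + d$t_hypo_l2
  d$t_hyper <- d$t_hyper_l1 + d$t_hyper_l2
  vars <- c("mean_glucose", "sd", "cv", "tir", "t_hyper", "t_hypo")
  rows <- lapply(split(d, d$participant_id), function(p) {
    out <- data.frame(participant_id = p$participant_id[1], nights = nrow(p))
    for (v in vars) {
      out[[paste0(v, "_mean")]] <- mean(p[[v]], na.rm = TRUE)
      out[[paste0(v, "_sd")]] <- if (nrow(p) > 1)
        stats::sd(p[[v]], na.rm = TRUE) else 0
    }
    out
  })
  participants <- do.call(rbind, rows)
  rownames(participants) <- NULL
  list(
    participants = participants,
    overall = cohort_overall(participants, count_cols = "nights")
  )
}
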