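#' Per-night sleep summary
#'
#' Computes the actigraphy summary variables for one night: total sleep time
#' (sum of non-wake minutes), time in bed, sleep efficiency
#' (100 * TST / TIB), WASO (wake minutes after sleep onset, the first
#' non-wake epoch), number of awakenings (wake bouts after onset, any
#' length), per-stage minutes and stage ratios over TST, Shannon entropy of
#' the night's 15-minute state sequence, and the 2-of-3 quality label from
#' [classify_quality()]. An all-wake night yields TST 0 and efficiency 0
#' without error.
#'
#' @param night A [hypnogram()].
#' @param entropy_mode Passed to [state_entropy()]; default `"transitions"`.
#' @return One-row data frame.
#' @export
night_summary <- function(night, entropy_mode = "transitions") {
  e <- night$epochs
  tib <- sum(e$duration_min)
  tst <- sum(e$duration_min[e$state != "wake"])
  onset <- match(TRUE, e$state != "wake")
  if (is.na(onset)) {
    waso <- 0; awakenings <- 0L
  } else {
    after <- seq_len(nrow(e)) > onset
    waso <- sum(e$duration_min[after & e$state == "wake"])
    awakenings <- sum(after & e$state == "wake")
  }
  stage_min <- vapply(SLEEP_STATES,
                      function(s) sum(e$duration_min[e$state == s]), 0)
  ratio <- if (tst > 0) 100 * stage_min[c("light", "deep", "rem")] / tst else
    c(light = 0, deep = 0, rem = 0)
  efficiency <- if (tib > 0) 100 * tst / tib else 0
  out <- data.frame(
    participant_id = night$participant_id,
    night_date = night$night_date,
    total_sleep_min = tst,
    time_in_bed_min = tib,
    efficiency = efficiency,
    waso_min = waso,
    n_awakenings = as.integer(awakenings),
    wake_min = stage_min[["wake"]],
    light_min = stage_min[["light"]],
    deep_min = stage_min[["deep"]],
    rem_min = stage_min[["rem"]],
    light_pct = ratio[["light"]],
    deep_pct = ratio[["deep"]],
    rem_pct = ratio[["rem"]],
    entropy_bits = state_entropy(night, mode = entropy_mode)
  )
  out$quality <- classify_quality(out$efficiency, out$waso_min,
                                  out$n_awakenings)
  rownames(out) <- NULL
  out
}

#' Night quality by the 2-of-3 consensus rule
#'
#' A night is `"poor"` when at least two of the three criteria hold:
#' sleep efficiency < 85%, WASO > 40 min, more than 4 awakenings. All three
#' comparisons are strict, so a night sitting exactly on every boundary is
#' `"good"`.
#'
#' @param efficiency Sleep efficiency in percent.
#' @param waso_min WASO in minutes.
#' @param n_awakenings Number of awakenings.
#' @return `"good"` or `"poor"` (vectorized).
#' @export
classify_quality <- function(efficiency, waso_min, n_awakenings) {
  n_bad <- (efficiency < 85) + (waso_min > 40) + (n_awakenings > 4)
  ifelse(n_bad >= 2, "poor", "good")
}

#' PSQI global score
#'
#' Sums the seven Pittsburgh Sleep Quality Index component scores (sleep
#' quality, latency, duration, habitual efficiency, disturbances, medication
#' use, daytime dysfunction), each on a 0-3 scale, into the 0-21 global
#' score; a global score above 5 flags a poor sleeper.
#'
#' @param components Numeric vector of 7 scores, or a data frame with seven
#'   component columns (extra columns such as `participant_id` pass
#'   through).
#' @param component_cols Column names when `components` is a data frame.
#' @return Data frame with `global` and `poor_sleeper` appended (one row per
#'   input row).
#' @export
psqi_global <- function(components,
                        component_cols = c("quality", "latency", "duration",
                                           "efficiency", "disturbances",
                                           "medication",
                                           "daytime_dysfunction")) {
  if (is.numeric(components)) {
    components <- as.data.frame(as.list(components),
                                col.names = component_cols)
  }
  sc <- components[, component_cols, drop = FALSE]
  vals <- as.matrix(sc)
  if (any(!is.na(vals) & (vals < 0 | vals > 3 | vals != round(vals)))) {
    stop("PSQI component scores must be integers in 0..3")
  }
  components$global <- rowSums(vals)
  components$poor_sleeper <- components$global > 5
  components
}

#' Shannon entropy of a night's state sequence
#'
#' Disorder of the night's 15-minute state sequence, in bits. In `"states"`
#' mode the entropy of the empirical distribution over the four stages
#' (range 0-2 bits); in `"transitions"` mode (default) the entropy of the
#' distribution of adjacent state pairs, which is sensitive to how often the
#' night switches stage, not just how long it spends in each (range 0-4
#' bits). A single-state night scores 0 in both modes.
#'
#' @param night A [hypnogram()].
#' @param mode `"transitions"` or `"states"`.
#' @param slot_minutes Slot length used to discretize the night.
#' @return Entropy in bits.
#' @export
state_entropy <- function(night, mode = c("transitions", "states"),
                          slot_minutes = 15) {
  mode <- match.arg(mode)
  s <- hypnogram_slots(night, slot_minutes)
  if (mode == "states") {
    return(shannon_entropy(table(factor(s, levels = SLEEP_STATES))))
  }
  if (length(s) < 2) return(0)
  pairs <- paste(s[-length(s)], s[-1])
  shannon_entropy(table(pairs))
}

#' Aggregate per-night sleep summaries to participant and cohort level
#'
#' Produces the participant-characteristics table (night counts, good/poor
#' counts, mean +/- SD of sleep hours, efficiency, WASO and awakenings) and
#' the stage-ratio table (mean percent of TST in light/deep/REM), each with
#' an overall row: counts are summed, everything else is the unweighted mean
#' of participant means (see [cohort_overall()]).
#'
#' @param night_summaries Data frame of [night_summary()] rows.
#' @return List with `participants`, `overall`, `stage_ratio`,
#'   `stage_ratio_overall`.
#' @export
aggregate_sleep <- function(night_summaries) {
  d <- night_summaries
  d$sleep_hours <- d$total_sleep_min / 60
  rows <- lapply(split(d, d$participant_id), function(p) {
    msd <- function(x) c(mean(x), if (nrow(p) > 1) stats::sd(x) else 0)
    h <- msd(p$sleep_hours); ef <- msd(p$efficiency)
    w <- msd(p$waso_min); a <- msd(p$n_awakenings)
    data.frame(
      participant_id = p$participant_id[1],
      nights = nrow(p),
      good = sum(p$quality == "good"),
      poor = sum(p$quality == "poor"),
      sleep_hours_mean = h[1], sleep_hours_sd = h[2],
      efficiency_mean = ef[1], efficiency_sd = ef[2],
      waso_mean = w[1], waso_sd = w[2],
      awakenings_mean = a[1], awakenings_sd = a[2]
    )
  })
  participants <- do.call(rbind, rows)
  rownames(participants) <- NULL
  ratio_rows <- lapply(split(d, d$participant_id), function(p) {
    data.frame(
      participant_id = p$participant_id[1],
      light_pct = mean(p$light_pct),
      deep_pct = mean(p$deep_pct),
      rem_pct = mean(p$rem_pct)
    )
  })
  stage_ratio <- do.call(rbind, ratio_rows)
  rownames(stage_ratio) <- NULL
  list(
    participants = participants,
    overall = cohort_overall(participants,
                             count_cols = c("nights", "good", "poor")),
    stage_ratio = stage_ratio,
    stage_ratio_overall = cohort_overall(stage_ratio)
  )
}
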