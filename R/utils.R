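`%||%` <- function(a, b) if (is.null(a)) b else a

# Nights are keyed by participant and date everywhere downstream.
night_id <- function(participant_id, night_date) {
  paste(participant_id, format(as.Date(night_date)), sep = "_")
}

# Round-half-up snapping of POSIXct times to a multiple of `sec` seconds.
# The 2.5-minute tie on a 5-minute grid rounds up.
snap_time <- function(time, sec) {
  as.POSIXct(floor(as.numeric(time) / sec + 0.5) * sec,
             origin = "1970-01-01", tz = "UTC")
}

local_time <- function(x, tz = "UTC") as.POSIXct(x, tz = tz)

minutes_of_day <- function(time) {
  lt <- as.POSIXlt(time, tz = "UTC")
  lt$hour * 60 + lt$min + lt$sec / 60
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Shannon entropy of a discrete distribution
#'
#' @param p Vector of probabilities or non-negative counts (normalized
#'   internally); zero cells contribute nothing.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(p) {
  p <- p[p > 0]
  if (!length(p)) return(0)
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Overall row of a per-participant summary table
#'
#' Cohort tables carry one row per participant; the overall row sums the
#' count columns and takes the unweighted mean of every other numeric column
#' (each participant contributes equally, regardless of how many nights they
#' recorded).
#'
#' @param tab Data frame with one row per participant.
#' @param count_cols Character vector of columns to sum rather than average.
#' @return One-row data frame with the same numeric columns.
#' @export
cohort_overall <- function(tab, count_cols = character()) {
  num <- vapply(tab, is.numeric, logical(1))
  out <- lapply(names(tab)[num], function(cl) {
    if (cl %in% count_cols) sum(tab[[cl]]) else mean(tab[[cl]])
  })
  names(out) <- names(tab)[num]
  as.data.frame(out)
}

#' Reference per-participant summary tables (HUPA cohort)
#'
#' Transcribed per-participant summary rows from a published observational
#' study of 22 adults with type 1 diabetes (243 nights) wearing flash CGM and
#' wrist actigraphy simultaneously: PSQI questionnaire component scores,
#' per-participant sleep-quality summaries, sleep-stage ratios over total
#' sleep time, and overnight glycemic characteristics. Useful as fixed inputs
#' for the aggregation operations and for PSQI scoring.
#'
#' @param table One of `"psqi"`, `"sleep_quality"`, `"stage_ratio"`,
#'   `"glycemia"`.
#' @return Data frame with one row per participant.
#' @export
hupa_reference <- function(table = c("psqi", "sleep_quality",
                                     "stage_ratio", "glycemia")) {
  table <- match.arg(table)
  path <- system.file("extdata", paste0("hupa_", table, ".csv"),
                      package = "noctiglyc", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
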