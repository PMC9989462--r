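# Fixture builders and independent brute-force oracles used across tests.
# Oracles are deliberately naive (per-minute loops, hand formulas) and share
# no code with the implementation they check.

t_utc <- function(x) as.POSIXct(x, tz = "UTC")

make_trace <- function(glucose, start = "2024-03-02 00:00:00",
                       by_min = 15, pid = "T001") {
  tm <- seq(t_utc(start), by = by_min * 60, length.out = length(glucose))
  glucose_trace(pid, tm, glucose, grid_minutes = by_min)
}

# Night built from a per-slot state sequence (15-min slots).
make_night <- function(states, date = "2024-03-02",
                       bed_start = "2024-03-01 23:00:00", pid = "T001") {
  r <- rle(states)
  starts <- t_utc(bed_start) + c(0, cumsum(r$lengths[-length(r$lengths)])) * 900
  hypnogram(pid, as.Date(date), r$values, starts, r$lengths * 15)
}

# A synthetic day_record with a directly specified 96-sample day grid,
# bypassing synchronization; used by motif/cluster tests.
make_day_record <- function(pid, date, glucose96) {
  tm <- seq(t_utc(paste(date, "00:00:00")), by = 900, length.out = 96)
  night <- make_night(rep("light", 28), date = date,
                      bed_start = paste(as.Date(date) - 1, "23:00:00"),
                      pid = pid)
  structure(
    list(participant_id = pid, night = night,
         day_glucose = data.frame(time = tm, glucose = glucose96),
         night_glucose = data.frame(time = tm[1:28], glucose = glucose96[1:28]),
         valid = TRUE, reason = NA_character_),
    class = "day_record"
  )
}

# --- independent oracles -------------------------------------------------

# Rosendaal interpolation by explicit per-minute segment walking.
oracle_interpolate <- function(times_min, glucose) {
  out_t <- seq(times_min[1], times_min[length(times_min)])
  out_g <- numeric(length(out_t))
  for (i in seq_along(out_t)) {
    t <- out_t[i]
    j <- max(which(times_min <= t))
    if (times_min[j] == t) {
      out_g[i] <- glucose[j]
    } else {
      f <- (t - times_min[j]) / (times_min[j + 1] - times_min[j])
      out_g[i] <- glucose[j] + f * (glucose[j + 1] - glucose[j])
    }
  }
  out_g
}

# Minute-counting range oracle.
oracle_ranges <- function(g) {
  n <- length(g)
  bands <- c(
    tir = sum(g >= 70 & g <= 180),
    t_hypo_l1 = sum(g >= 55 & g < 70),
    t_hypo_l2 = sum(g < 55),
    t_hyper_l1 = sum(g > 180 & g <= 250),
    t_hyper_l2 = sum(g > 250)
  )
  100 * bands / n
}

# Run-length episode oracle via an explicit scan.
oracle_episodes <- function(flags, min_len = 15) {
  count <- 0; run <- 0
  for (f in c(flags, FALSE)) {
    if (f) run <- run + 1
    else { if (run >= min_len) count <- count + 1; run <- 0 }
  }
  count
}

# MAGE oracle: same definition, independent mechanics -- smooth with an
# explicit loop, find local extrema by neighbour comparison on the
# plateau-collapsed series, average qualifying |swings|.
oracle_mage <- function(g, k = 3) {
  n <- length(g)
  sm <- g
  half <- (k - 1) / 2
  for (i in (1 + half):(n - half)) sm[i] <- mean(g[(i - half):(i + half)])
  vals <- sm[c(TRUE, diff(sm) != 0)]
  if (length(vals) < 2) return(NA_real_)
  ext <- vals[1]
  for (i in 2:(length(vals) - 1)) {
    if ((vals[i] > vals[i - 1] && vals[i] > vals[i + 1]) ||
        (vals[i] < vals[i - 1] && vals[i] < vals[i + 1])) {
      ext <- c(ext, vals[i])
    }
  }
  ext <- c(ext, vals[length(vals)])
  amps <- abs(diff(ext))
  amps <- amps[amps > sd(g) + 1e-9]
  if (!length(amps)) return(NA_real_) else mean(amps)
}

# PAA oracle with an explicit block loop.
oracle_paa <- function(x, f) {
  if (length(x) %% f != 0) x <- c(x, rep(x[length(x)], f - length(x) %% f))
  vapply(seq_len(length(x) / f),
         function(b) mean(x[((b - 1) * f + 1):(b * f)]), 0)
}

# TF-IDF oracle with nested loops over a list of word vectors.
oracle_tfidf <- function(corpora) {
  vocab <- sort(unique(unlist(corpora)))
  K <- length(corpora)
  w <- matrix(0, K, length(vocab), dimnames = list(names(corpora), vocab))
  for (v in vocab) {
    df <- sum(vapply(corpora, function(cc) v %in% cc, logical(1)))
    idf <- log(K / df)
    for (ci in seq_len(K)) {
      tf <- sum(corpora[[ci]] == v) / length(corpora[[ci]])
      w[ci, v] <- tf * idf
    }
  }
  w
}

random_word_corpora <- function(k = 3, vocab_size = 6, n_words = 20) {
  vocab <- replicate(vocab_size, paste(sample(letters[1:4], 3, TRUE),
                                       collapse = ""))
  out <- lapply(seq_len(k), function(i) sample(vocab, n_words, replace = TRUE))
  names(out) <- paste0("c", seq_len(k))
  out
}
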