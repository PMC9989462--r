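#' Markov transition model over sleep states
#'
#' Sleep structure is modelled as a first-order Markov chain over the four
#' stages in [SLEEP_STATES], stepping once per 15-minute epoch. The
#' transition matrix is row-stochastic; the initial distribution gives the
#' state of the first epoch after getting into bed.
#'
#' @param transition_matrix 4x4 row-stochastic matrix, rows/cols ordered as
#'   [SLEEP_STATES].
#' @param initial_distribution Length-4 probability vector (default: start
#'   awake or in light sleep with equal probability).
#' @return Object of class `transition_model`.
#' @export
transition_model <- function(transition_matrix,
                             initial_distribution = c(0.5, 0.5, 0, 0)) {
  tm <- as.matrix(transition_matrix)
  if (!all(dim(tm) == c(4, 4))) stop("transition_matrix must be 4x4")
  if (any(tm < 0)) stop("transition probabilities must be non-negative")
  if (any(abs(rowSums(tm) - 1) > 1e-9)) {
    stop("each transition_matrix row must sum to 1")
  }
  if (any(initial_distribution < 0) ||
      abs(sum(initial_distribution) - 1) > 1e-9) {
    stop("initial_distribution must be a probability vector")
  }
  dimnames(tm) <- list(SLEEP_STATES, SLEEP_STATES)
  structure(
    list(states = SLEEP_STATES, transition_matrix = tm,
         initial_distribution = initial_distribution),
    class = "transition_model"
  )
}

#' Stationary distribution of a transition model
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalized to
#' sum to one. Used as an independent check that simulated state fractions
#' converge where expected.
#'
#' @param model A [transition_model()].
#' @return Named probability vector over [SLEEP_STATES].
#' @export
stationary_distribution <- function(model) {
  e <- eigen(t(model$transition_matrix))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  names(v) <- SLEEP_STATES
  v
}

#' Built-in sleep-structure archetypes
#'
#' Four qualitatively distinct night archetypes, chosen to span the patterns
#' wrist actigraphy typically reports in adults: a fragmented sleeper with
#' frequent awakenings and stage changes, a consolidated sleeper with long
#' stable light-sleep runs, and two cyclers whose light sleep alternates
#' predominantly with deep or with REM sleep. Their transition matrices are
#' well separated in transition-count space, so they serve as planted ground
#' truth for clustering-recovery experiments.
#'
#' @return Named list of four [transition_model()] objects.
#' @export
sleep_archetypes <- function() {
  list(
    fragmented = transition_model(rbind(
      c(0.50, 0.30, 0.10, 0.10),
      c(0.30, 0.40, 0.15, 0.15),
      c(0.30, 0.40, 0.25, 0.05),
      c(0.30, 0.40, 0.05, 0.25)
    )),
    consolidated = transition_model(rbind(
      c(0.10, 0.90, 0.00, 0.00),
      c(0.02, 0.90, 0.04, 0.04),
      c(0.01, 0.29, 0.70, 0.00),
      c(0.01, 0.29, 0.00, 0.70)
    )),
    deep_cycler = transition_model(rbind(
      c(0.10, 0.60, 0.30, 0.00),
      c(0.03, 0.27, 0.68, 0.02),
      c(0.02, 0.58, 0.40, 0.00),
      c(0.05, 0.55, 0.10, 0.30)
    )),
    rem_cycler = transition_model(rbind(
      c(0.10, 0.60, 0.00, 0.30),
      c(0.03, 0.27, 0.02, 0.68),
      c(0.03, 0.62, 0.35, 0.00),
      c(0.02, 0.58, 0.00, 0.40)
    ))
  )
}

#' Simulation parameters for the synthetic cohort
#'
#' Defaults emulate the recording setup the pipeline targets: 22 participants
#' wearing both devices for about two weeks (6-16 analyzable nights each),
#' glucose on a 15-minute grid (96 samples/day), and nights of 40-44
#' 15-minute sleep epochs. Glucose is basal + circadian sinusoid + meal
#' excursions + Gaussian noise; the nocturnal noise SD is inflated by
#' `coupling` mg/dl per lost point of sleep efficiency, which plants the
#' sleep-variability/glucose-variability association the analysis is designed
#' to detect.
#'
#' @param n_participants Number of participants.
#' @param nights_min,nights_max Range of analyzable nights per participant.
#' @param epoch_minutes Sleep epoch length (minutes).
#' @param night_slots Maximum epochs per night; actual nights draw uniformly
#'   from `night_slots - 4` to `night_slots`.
#' @param glucose_grid_minutes CGM cadence (minutes).
#' @param archetypes Named list of [transition_model()] objects.
#' @param archetype_weights Sampling probabilities over archetypes (sum 1).
#' @param coupling Nocturnal noise-SD inflation, mg/dl per percentage point
#'   of sleep efficiency below 100.
#' @param meal_times Hours of day of meal excursion centers.
#' @param meal_amplitude Meal excursion peak height, mg/dl.
#' @param meal_width_min Meal excursion Gaussian SD, minutes.
#' @param basal_mean Basal glucose level, mg/dl.
#' @param circadian_amplitude Amplitude of the 24-h sinusoid, mg/dl.
#' @param noise_sd Baseline measurement/physiology noise SD, mg/dl.
#' @param start_date Calendar date of the first simulated night.
#' @param seed Integer seed; every stochastic draw flows from it.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(n_participants = 22,
                       nights_min = 6, nights_max = 16,
                       epoch_minutes = 15,
                       night_slots = 44,
                       glucose_grid_minutes = 15,
                       archetypes = sleep_archetypes(),
                       archetype_weights = rep(1 / length(archetypes),
                                               length(archetypes)),
                       coupling = 2.0,
                       meal_times = c(7.5, 13.0, 20.5),
                       meal_amplitude = 60,
                       meal_width_min = 45,
                       basal_mean = 140,
                       circadian_amplitude = 10,
                       noise_sd = 10,
                       start_date = as.Date("2024-03-01"),
                       seed = 1L) {
  stopifnot(n_participants >= 1, nights_min >= 1, nights_max >= nights_min,
            night_slots > 0, basal_mean > 0, coupling >= 0, noise_sd >= 0)
  if (abs(sum(archetype_weights) - 1) > 1e-9 || any(archetype_weights < 0)) {
    stop("archetype_weights must be a probability vector summing to 1")
  }
  if (length(archetype_weights) != length(archetypes)) {
    stop("one weight per archetype is required")
  }
  ok <- vapply(archetypes, inherits, logical(1), "transition_model")
  if (!all(ok)) stop("archetypes must be transition_model objects")
  structure(
    list(
      n_participants = n_participants, nights_min = nights_min,
      nights_max = nights_max, epoch_minutes = epoch_minutes,
      night_slots = night_slots,
      glucose_grid_minutes = glucose_grid_minutes,
      archetypes = archetypes, archetype_weights = archetype_weights,
      coupling = coupling, meal_times = meal_times,
      meal_amplitude = meal_amplitude, meal_width_min = meal_width_min,
      basal_mean = basal_mean, circadian_amplitude = circadian_amplitude,
      noise_sd = noise_sd, start_date = as.Date(start_date),
      seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

#' Simulate one night's hypnogram from a Markov model
#'
#' Draws `n_slots` epoch states from the chain and merges consecutive equal
#' states into epochs. Deterministic given `seed`; with `seed = NULL` the
#' current RNG stream is used (as [simulate_cohort()] does, so one cohort
#' seed governs everything).
#'
#' @param model A [transition_model()].
#' @param n_slots Number of epochs to draw (>= 1).
#' @param seed Integer seed or `NULL`.
#' @param participant_id,night_date,bed_start Identity and timing of the
#'   night; `bed_start` defaults to 23:00 on the evening before `night_date`.
#' @param epoch_minutes Epoch length in minutes.
#' @return A [hypnogram()].
#' @export
simulate_hypnogram <- function(model, n_slots, seed = NULL,
                               participant_id = "SIM001",
                               night_date = as.Date("2024-03-02"),
                               bed_start = NULL,
                               epoch_minutes = 15) {
  stopifnot(inherits(model, "transition_model"), n_slots >= 1)
  night_date <- as.Date(night_date)
  bed_start <- bed_start %||%
    (local_time(paste(night_date - 1, "23:00:00")))
  draw <- function() {
    s <- integer(n_slots)
    s[1] <- sample.int(4, 1, prob = model$initial_distribution)
    for (i in seq_len(n_slots - 1)) {
      s[i + 1] <- sample.int(4, 1, prob = model$transition_matrix[s[i], ])
    }
    SLEEP_STATES[s]
  }
  states <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  ep <- slots_to_epochs(states, bed_start, epoch_minutes)
  hypnogram(participant_id, night_date, ep$state, ep$start, ep$duration_min)
}

# Deterministic part of the glucose model: basal + circadian + meals.
glucose_mean_curve <- function(params, time) {
  h <- minutes_of_day(time) / 60
  circ <- params$circadian_amplitude * sin(2 * pi * (h - 10) / 24)
  meal <- rep(0, length(h))
  for (m in params$meal_times) {
    meal <- meal + params$meal_amplitude *
      exp(-0.5 * ((h - m) * 60 / params$meal_width_min)^2)
  }
  params$basal_mean + circ + meal
}

hypnogram_efficiency <- function(night) {
  tib <- sum(night$epochs$duration_min)
  tst <- sum(night$epochs$duration_min[night$epochs$state != "wake"])
  if (tib == 0) 0 else 100 * tst / tib
}

#' Simulate a glucose trace paired with one or more nights
#'
#' Produces a continuous 15-minute glucose series for one participant,
#' running from 22:00 on the evening before the first night through 23:45 on
#' the last night's date (so each night's calendar day carries its full 96
#' samples). The series is basal + circadian sinusoid + Gaussian meal
#' excursions + Gaussian noise; samples falling inside a night's bed window
#' have their noise SD inflated additively by
#' `coupling * (100 - that night's sleep efficiency)` mg/dl. Values are
#' clipped to the 40-400 mg/dl sensor dynamic range and rounded to integer
#' mg/dl as a flash CGM reports them.
#'
#' @param params A [sim_params()].
#' @param nights A single [hypnogram()] or a list of them (one participant,
#'   distinct dates).
#' @param seed Integer seed or `NULL` to use the current RNG stream.
#' @return A [glucose_trace()].
#' @export
simulate_glucose <- function(params, nights, seed = NULL) {
  if (inherits(nights, "hypnogram")) nights <- list(nights)
  stopifnot(length(nights) >= 1)
  dates <- as.Date(vapply(nights, function(n) as.character(n$night_date), ""))
  pid <- nights[[1]]$participant_id
  t0 <- local_time(paste(min(dates) - 1, "22:00:00"))
  t1 <- local_time(paste(max(dates), "23:45:00"))
  grid <- seq(t0, t1, by = params$glucose_grid_minutes * 60)
  base <- glucose_mean_curve(params, grid)
  sdv <- rep(params$noise_sd, length(grid))
  for (n in nights) {
    idx <- grid >= n$bed_start & grid <= n$bed_end
    eff <- hypnogram_efficiency(n)
    sdv[idx] <- params$noise_sd + params$coupling * (100 - eff)
  }
  draw <- function() stats::rnorm(length(grid), 0, sdv)
  noise <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  g <- round(pmin(400, pmax(40, base + noise)))
  glucose_trace(pid, grid, g, params$glucose_grid_minutes)
}

#' Simulate a full paired sleep/CGM cohort
#'
#' Each participant is assigned one sleep archetype (sampled by
#' `archetype_weights`), then records `nights_min`-`nights_max` consecutive
#' nights of 40-44 epochs with a jittered bed time, plus one continuous
#' glucose trace covering the whole recording. The planted archetype of every
#' night is returned as ground truth for clustering-recovery experiments.
#'
#' @param params A [sim_params()].
#' @return A list of class `synthetic_cohort` with elements `params`,
#'   `participants` (id, archetype), `nights` (list of [hypnogram()]),
#'   `glucose` (named list of per-participant [glucose_trace()]) and
#'   `ground_truth` (participant_id, night_date, archetype).
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  arch_names <- names(params$archetypes)
  withr::with_seed(params$seed, {
    pids <- sprintf("SIM%03d", seq_len(params$n_participants))
    arch <- arch_names[sample.int(
      length(arch_names), params$n_participants,
      replace = TRUE, prob = params$archetype_weights
    )]
    nights <- list()
    glucose <- list()
    gt <- list()
    for (p in seq_along(pids)) {
      n_nights <- if (params$nights_min == params$nights_max) {
        params$nights_min
      } else {
        sample(params$nights_min:params$nights_max, 1)
      }
      p_nights <- vector("list", n_nights)
      for (k in seq_len(n_nights)) {
        n_slots <- sample(max(1, params$night_slots - 4):params$night_slots, 1)
        date_k <- params$start_date + k
        bed_start <- local_time(paste(date_k - 1, "22:00:00")) +
          sample(0:11, 1) * 300
        p_nights[[k]] <- simulate_hypnogram(
          params$archetypes[[arch[p]]], n_slots,
          participant_id = pids[p], night_date = date_k,
          bed_start = bed_start, epoch_minutes = params$epoch_minutes
        )
      }
      nights <- c(nights, p_nights)
      glucose[[pids[p]]] <- simulate_glucose(params, p_nights)
      gt[[p]] <- data.frame(
        participant_id = pids[p],
        night_date = as.Date(vapply(p_nights,
                                    function(n) as.character(n$night_date), "")),
        archetype = arch[p]
      )
    }
    structure(
      list(
        params = params,
        participants = data.frame(participant_id = pids, archetype = arch),
        nights = nights,
        glucose = glucose,
        ground_truth = do.call(rbind, gt)
      ),
      class = "synthetic_cohort"
    )
  })
}

#' Write a synthetic cohort in the device-export dialects
#'
#' Writes, per participant, a CGM CSV in the flash-meter export dialect and a
#' sleep-log JSON in the wrist-tracker dialect that [read_cgm_csv()] and
#' [read_sleep_json()] consume, plus a `ground_truth.csv` sidecar
#' (participant_id, night_date, archetype). Round-trip through the readers
#' reproduces the in-memory objects.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pid in cohort$participants$participant_id) {
    tr <- cohort$glucose[[pid]]
    df <- data.frame(
      Device = "FreeStyle Libre",
      `Serial Number` = pid,
      `Device Timestamp` = format(tr$samples$time, "%d-%m-%Y %H:%M"),
      `Record Type` = 0L,
      `Historic Glucose mg/dL` = tr$samples$glucose,
      check.names = FALSE
    )
    utils::write.csv(df, file.path(dir, paste0(pid, "_cgm.csv")),
                     row.names = FALSE)
    p_nights <- Filter(function(n) n$participant_id == pid, cohort$nights)
    logs <- lapply(p_nights, function(n) {
      list(
        dateOfSleep = format(n$night_date),
        isMainSleep = TRUE,
        levels = list(data = lapply(seq_len(nrow(n$epochs)), function(i) {
          list(
            dateTime = format(n$epochs$start[i], "%Y-%m-%dT%H:%M:%S.000"),
            level = n$epochs$state[i],
            seconds = n$epochs$duration_min[i] * 60
          )
        }))
      )
    })
    jsonlite::write_json(logs, file.path(dir, paste0(pid, "_sleep.json")),
                         auto_unbox = TRUE, pretty = FALSE)
  }
  gt <- cohort$ground_truth
  gt$night_date <- format(gt$night_date)
  utils::write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(dir)
}
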