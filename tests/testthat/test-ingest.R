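write_cgm_fixture <- function(rows, path = tempfile(fileext = ".csv")) {
  header <- "Device,Serial Number,Device Timestamp,Record Type,Historic Glucose mg/dL"
  writeLines(c(header, rows), path)
  path
}

test_that("CGM CSV parsing keeps historic rows, sorts and deduplicates", {
  path <- write_cgm_fixture(c(
    "FreeStyle Libre,P01,02-03-2024 08:15,0,120",
    "FreeStyle Libre,P01,02-03-2024 08:00,0,110",
    "FreeStyle Libre,P01,02-03-2024 08:30,0,130",
    "FreeStyle Libre,P01,02-03-2024 08:00,0,999",
    "FreeStyle Libre,P01,02-03-2024 08:45,1,140"
  ))
  tr <- read_cgm_csv(path)
  expect_s3_class(tr, "glucose_trace")
  expect_equal(tr$participant_id, "P01")
  # scan rows sorted ascending, duplicate 08:00 keeps the first-seen
  # occurrence (110 precedes 999 after the stable sort), type-1 row dropped
  expect_equal(tr$samples$glucose, c(110, 120, 130))
  expect_true(all(diff(tr$samples$time) > 0))
})

test_that("malformed CGM rows land in the rejects report, empty files error", {
  path <- write_cgm_fixture(c(
    "FreeStyle Libre,P01,02-03-2024 08:00,0,110",
    "FreeStyle Libre,P01,not-a-time,0,115",
    "FreeStyle Libre,P01,02-03-2024 08:30,0,abc"
  ))
  tr <- read_cgm_csv(path)
  expect_equal(nrow(tr$samples), 1)
  rej <- attr(tr, "rejects")
  expect_equal(nrow(rej), 2)
  expect_setequal(rej$reason, c("bad_timestamp", "bad_glucose"))

  empty <- write_cgm_fixture(character(0))
  expect_error(read_cgm_csv(empty), "empty")
  expect_error(read_cgm_csv(tempfile()), "no such file")
})

test_that("sleep JSON parsing maps stages and skips naps", {
  logs <- list(
    list(dateOfSleep = "2024-03-02", isMainSleep = TRUE,
         levels = list(data = list(
           list(dateTime = "2024-03-01T23:00:00.000", level = "light",
                seconds = 300 * 60)
         ))),
    list(dateOfSleep = "2024-03-02", isMainSleep = FALSE,
         levels = list(data = list(
           list(dateTime = "2024-03-02T14:00:00.000", level = "light",
                seconds = 3600)
         )))
  )
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(logs, path, auto_unbox = TRUE)
  hyps <- read_sleep_json(path, participant_id = "P01")
  expect_length(hyps, 1)
  expect_equal(nrow(hyps[[1]]$epochs), 1)
  expect_equal(hyps[[1]]$epochs$duration_min, 300)

  logs[[1]]$levels$data[[1]]$level <- "hypnopompic"
  jsonlite::write_json(logs, path, auto_unbox = TRUE)
  expect_error(read_sleep_json(path), "hypnopompic")
})

test_that("synthetic cohort round-trips through the device dialects", {
  co <- simulate_cohort(sim_params(n_participants = 2, nights_min = 2,
                                   nights_max = 3, seed = 31))
  dir <- tempfile()
  write_cohort(co, dir)
  for (pid in co$participants$participant_id) {
    tr <- read_cgm_csv(file.path(dir, paste0(pid, "_cgm.csv")))
    expect_identical(tr$samples, co$glucose[[pid]]$samples)
    hyps <- read_sleep_json(file.path(dir, paste0(pid, "_sleep.json")))
    orig <- Filter(function(n) n$participant_id == pid, co$nights)
    expect_length(hyps, length(orig))
    for (i in seq_along(orig)) {
      expect_identical(hyps[[i]]$epochs, orig[[i]]$epochs)
    }
  }
  # write -> read -> write is byte-stable
  co2 <- list(params = co$params, participants = co$participants,
              nights = unlist(lapply(co$participants$participant_id,
                                     function(p) read_sleep_json(
                                       file.path(dir, paste0(p, "_sleep.json")),
                                       participant_id = p)),
                              recursive = FALSE),
              glucose = setNames(lapply(co$participants$participant_id,
                                        function(p) read_cgm_csv(
                                          file.path(dir, paste0(p, "_cgm.csv")))),
                                 co$participants$participant_id),
              ground_truth = co$ground_truth)
  class(co2) <- "synthetic_cohort"
  dir2 <- tempfile()
  write_cohort(co2, dir2)
  for (f in list.files(dir, pattern = "csv$|json$")) {
    expect_identical(readLines(file.path(dir2, f)),
                     readLines(file.path(dir, f)), label = f)
  }
})

test_that("timestamps snap to the nearest 5-minute multiple, ties up", {
  snap <- noctiglyc:::snap_time
  expect_equal(snap(t_utc("2024-03-02 14:03:00"), 300),
               t_utc("2024-03-02 14:05:00"))
  expect_equal(snap(t_utc("2024-03-02 14:02:00"), 300),
               t_utc("2024-03-02 14:00:00"))
  expect_equal(snap(t_utc("2024-03-02 14:02:30"), 300),
               t_utc("2024-03-02 14:05:00"))
})

test_that("synchronization is idempotent on aligned data and bins stages", {
  g <- make_trace(rep(100, 96), start = "2024-03-02 00:00:00")
  night <- make_night(rep("light", 28))
  rec <- synchronize(g, night)
  expect_true(rec$valid)
  expect_equal(rec$day_glucose$glucose, rep(100, 96))
  expect_identical(rec$night$epochs, night$epochs)

  # three 5-min epochs light/light/wake inside one 15-min bin
  h <- hypnogram("T001", "2024-03-02",
                 c("light", "wake"),
                 t_utc(c("2024-03-02 01:00:00", "2024-03-02 01:10:00")),
                 c(10, 5))
  rec2 <- synchronize(g, h)
  expect_equal(rec2$night_bins$light_min, 10)
  expect_equal(rec2$night_bins$wake_min, 5)
  expect_equal(rec2$night_bins$state, "light")
})

test_that("off-grid glucose is resampled to the 15-minute day grid", {
  tm <- t_utc("2024-03-02 00:03:00") + seq(0, 95) * 900
  tr <- glucose_trace("T001", tm, rep(100, 96))
  rec <- synchronize(tr, make_night(rep("light", 28)))
  # 00:03 snaps to 00:05, within 7.5 min of the 00:00 grid slot
  expect_equal(sum(!is.na(rec$day_glucose$glucose)), 96)
})

test_that("day filtering applies the gap and nocturnal-window rules", {
  vals <- rep(100, 96)
  night <- make_night(rep("light", 28))

  gap100 <- vals; gap100[10:15] <- NA  # 6 missing slots: 105-min gap
  rec_a <- synchronize(make_trace(gap100), night)
  gap90 <- vals; gap90[10:14] <- NA    # 5 missing slots: exactly 90 min
  rec_b <- synchronize(make_trace(gap90), night)
  nap <- make_night(rep("light", 8), bed_start = "2024-03-02 13:00:00")
  rec_c <- synchronize(make_trace(vals), nap)

  flt <- filter_days(list(rec_a, rec_b, rec_c))
  expect_equal(length(flt$kept) + nrow(flt$discarded), 3)
  expect_equal(nrow(flt$discarded), 2)
  expect_setequal(flt$discarded$reason, c("glucose_gap", "not_nocturnal"))
  kept_dates <- vapply(flt$kept, function(r) r$night$bed_start == night$bed_start,
                       logical(1))
  expect_true(all(kept_dates))
})

test_that("a gapless synthetic cohort passes the filters in full", {
  co <- simulate_cohort(sim_params(n_participants = 3, nights_min = 3,
                                   nights_max = 5, seed = 77))
  recs <- lapply(co$nights, function(n) {
    synchronize(co$glucose[[n$participant_id]], n)
  })
  flt <- filter_days(recs)
  expect_length(flt$kept, length(recs))
  expect_equal(nrow(flt$discarded), 0)
})
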