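test_that("per-minute interpolation reproduces hand values", {
  tr <- make_trace(rep(100, 5))
  m <- interpolate_minutes(tr)
  expect_equal(nrow(m), 61)
  expect_true(all(m$glucose == 100))

  tr2 <- make_trace(c(100, 160), by_min = 30)
  m2 <- interpolate_minutes(tr2)
  expect_equal(m2$glucose[16], 130)  # minute 15 on the line

  expect_error(interpolate_minutes(make_trace(100)), "two")
})

test_that("interpolation matches the brute-force per-minute oracle", {
  withr::with_seed(101, {
    for (i in 1:50) {
      n <- sample(3:12, 1)
      times <- cumsum(c(0, sample(1:30, n - 1, TRUE)))
      g <- runif(n, 50, 300)
      tm <- t_utc("2024-03-02 00:00:00") + times * 60
      m <- interpolate_minutes(data.frame(time = tm, glucose = g))
      expect_lt(max(abs(m$glucose - oracle_interpolate(times, g))), 1e-9)
    }
  })
})

test_that("time in ranges partitions the day and matches minute counting", {
  expect_equal(unname(time_in_ranges(rep(100, 60))["tir"]), 100)
  expect_equal(sum(time_in_ranges(rep(100, 60))), 100)

  ramp <- seq(60, 180, length.out = 121)  # linear 60 -> 180 over 120 min
  expect_equal(unname(time_in_ranges(ramp)), unname(oracle_ranges(ramp)))

  withr::with_seed(102, {
    for (i in 1:50) {
      g <- runif(200, 30, 350)
      r <- time_in_ranges(g)
      expect_equal(sum(r), 100, tolerance = 1e-6)
      expect_equal(unname(r), unname(oracle_ranges(g)))
    }
  })
})

test_that("basic stats follow the sample-SD convention", {
  expect_equal(unname(basic_stats(rep(140, 10))), c(140, 0, 0))
  two <- basic_stats(c(100, 200))
  expect_equal(unname(two["mean"]), 150)
  expect_equal(unname(two["sd"]), sd(c(100, 200)))
  expect_equal(unname(two["cv"]), 100 * sd(c(100, 200)) / 150)
  expect_equal(unname(basic_stats(rep(c(80, 120), 30))["mean"]), 100)
  pop <- basic_stats(c(100, 200), sd_type = "population")
  expect_equal(unname(pop["sd"]), 50)
})

test_that("episode counting respects the 15-minute minimum", {
  base <- rep(100, 120)
  expect_equal(count_episodes(base, function(g) g < 70), 0L)
  dip20 <- base; dip20[30:49] <- 60
  expect_equal(count_episodes(dip20, function(g) g < 70), 1L)
  dip10 <- base; dip10[30:39] <- 60
  expect_equal(count_episodes(dip10, function(g) g < 70), 0L)

  withr::with_seed(103, {
    for (i in 1:50) {
      g <- 100 + cumsum(rnorm(300, 0, 8))
      flags <- g > 180
      expect_equal(count_episodes(g, function(x) x > 180),
                   oracle_episodes(flags))
    }
  })
})

test_that("MAGE matches hand-built excursion cases", {
  expect_true(is.na(mage(rep(120, 200))))

  sq <- rep(rep(c(100, 200), each = 60), 5)  # square wave, SD < 100
  expect_lt(abs(mage(sq) - 100), 1)

  t <- seq(0, 24, length.out = 1441)
  sine <- 150 + 60 * cos(2 * pi * t / 8)     # three cycles, amplitude 60
  expect_lt(abs(mage(sine) - 120), 2)        # peak-to-nadir is 2A
})

test_that("MAGE is shift-invariant, scales linearly, and matches the oracle", {
  withr::with_seed(104, {
    for (i in 1:30) {
      g <- 150 + 50 * sin(seq(0, 6 * pi, length.out = 400)) + rnorm(400, 0, 5)
      m <- mage(g)
      expect_equal(mage(g + 35), m, tolerance = 1e-9)
      expect_equal(mage(g * 1.7) / 1.7, m, tolerance = 1e-9)
      expect_equal(m, oracle_mage(g), tolerance = 1e-9)
    }
  })
})

test_that("MDGD matches element-wise differencing at equal clock times", {
  d1 <- interpolate_minutes(make_trace(runif(96, 80, 200),
                                       start = "2024-03-02 00:00:00"))
  d2 <- d1
  d2$time <- d2$time + 86400
  expect_equal(mdgd(d1, d2), 0)
  d3 <- d2; d3$glucose <- d3$glucose + 10
  expect_equal(mdgd(d1, d3), 10)

  withr::with_seed(105, {
    g1 <- runif(500, 60, 250); g2 <- runif(500, 60, 250)
    a <- data.frame(time = t_utc("2024-03-02 01:00:00") + (0:499) * 60,
                    glucose = g1)
    b <- data.frame(time = t_utc("2024-03-03 01:00:00") + (0:499) * 60,
                    glucose = g2)
    expect_equal(mdgd(a, b), mean(abs(g2 - g1)))
  })

  off <- data.frame(time = t_utc("2024-03-03 20:00:00") + (0:59) * 60,
                    glucose = runif(60))
  expect_error(mdgd(d1[1:60, ], off), "clock")
  expect_true(is.na(mdgd_multi(list(d1))))
  expect_equal(mdgd_multi(list(d1, d2, d3)), 5)
})

test_that("day summaries populate every field consistently", {
  rec <- make_day_record("P1", "2024-03-02", rep(100, 96))
  s <- summarize_day(rec, window = "day")
  expect_equal(s$mean_glucose, 100)
  expect_equal(s$tir, 100)
  expect_equal(s$sd, 0)
  expect_equal(s$n_hypo_episodes + s$n_hyper_episodes, 0L)
  expect_true(is.na(s$mage))

  varied <- 140 + 80 * sin(2 * pi * (0:95) / 32)
  rec2 <- make_day_record("P1", "2024-03-03", varied)
  s_day <- summarize_day(rec2, window = "day")
  s_night <- summarize_day(rec2, window = "night")
  expect_false(isTRUE(all.equal(s_day$mean_glucose, s_night$mean_glucose)))

  minutes <- interpolate_minutes(rec2$day_glucose)
  expect_equal(s_day$mean_glucose, mean(minutes$glucose))
  expect_equal(unname(s_day$tir),
               unname(oracle_ranges(minutes$glucose)["tir"]))
  expect_equal(s_day$mage, oracle_mage(minutes$glucose))

  bad <- rec; bad$valid <- FALSE
  expect_error(summarize_day(bad), "invalid")
})

test_that("cohort aggregation is unweighted and permutation-invariant", {
  withr::with_seed(106, {
    days <- do.call(rbind, lapply(1:4, function(p) {
      do.call(rbind, lapply(1:5, function(d) {
        rec <- make_day_record(paste0("P", p),
                               as.Date("2024-03-01") + d,
                               runif(96, 70, 250))
        summarize_day(rec, window = "day")
      }))
    }))
  })
  agg <- aggregate_glycemia(days)
  expect_equal(agg$overall$nights, 20)
  expect_equal(agg$overall$tir_mean, mean(agg$participants$tir_mean))

  shuffled <- days[sample(nrow(days)), ]
  agg2 <- aggregate_glycemia(shuffled)
  expect_equal(agg$overall, agg2$overall)

  solo <- aggregate_glycemia(days[days$participant_id == "P1", ])
  expect_equal(solo$overall$mean_glucose_mean,
               solo$participants$mean_glucose_mean[1])
})
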