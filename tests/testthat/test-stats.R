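make_cohort_tables <- function(seed = 117) {
  co <- simulate_cohort(sim_params(n_participants = 8, nights_min = 4,
                                   nights_max = 6, seed = seed))
  recs <- lapply(co$nights, function(n)
    synchronize(co$glucose[[n$participant_id]], n))
  sleep_agg <- aggregate_sleep(do.call(rbind, lapply(co$nights, night_summary)))
  glyc <- do.call(rbind, lapply(recs, summarize_day, window = "night"))
  list(sleep = sleep_agg, glyc = aggregate_glycemia(glyc), daily = glyc)
}

test_that("the participant variable table matches a direct group-by", {
  tabs <- make_cohort_tables()
  vt <- build_variable_table(tabs$sleep, tabs$glyc)
  expect_equal(nrow(vt), 8)
  expect_false(anyNA(vt[, sapply(vt, is.numeric)]))

  # direct group-by oracle for one participant and two columns
  pid <- vt$participant_id[1]
  daily <- tabs$daily[tabs$daily$participant_id == pid, ]
  expect_equal(vt$mean_glucose_mean[vt$participant_id == pid],
               mean(daily$mean_glucose))
  expect_equal(vt$mean_glucose_sd[vt$participant_id == pid],
               sd(daily$mean_glucose))

  # participants with a single night carry no SDs and are dropped
  solo <- tabs$sleep
  solo$participants$nights[1] <- 1
  vt2 <- build_variable_table(solo, tabs$glyc)
  expect_equal(nrow(vt2), 7)
})

test_that("the correlogram is symmetric with unit diagonal and sane bounds", {
  withr::with_seed(118, {
    tab <- data.frame(x = rnorm(20))
    tab$y <- tab$x
    tab$z <- -tab$x
    tab$w <- rnorm(20)
    tab$const <- 5
  })
  m <- pearson_correlogram(tab)
  expect_equal(m["x", "y"], 1)
  expect_equal(m["x", "z"], -1)
  expect_equal(m, t(m))
  expect_true(all(is.na(m["const", ])))
  sub <- m[c("x", "y", "z", "w"), c("x", "y", "z", "w")]
  expect_equal(diag(sub), c(x = 1, y = 1, z = 1, w = 1))
  expect_true(all(abs(sub) <= 1 + 1e-12))
  expect_gte(min(eigen(sub, only.values = TRUE)$values), -1e-9)
  expect_error(pearson_correlogram(tab[1:2, ]), "3")
})

test_that("planted sleep-glucose coupling is recovered in the correlogram", {
  co <- simulate_cohort(sim_params(coupling = 2.0, seed = 119))
  recs <- lapply(co$nights, function(n)
    synchronize(co$glucose[[n$participant_id]], n))
  sleep_agg <- aggregate_sleep(do.call(rbind, lapply(co$nights, night_summary)))
  glyc_agg <- aggregate_glycemia(
    do.call(rbind, lapply(recs, summarize_day, window = "night")))
  vt <- build_variable_table(sleep_agg, glyc_agg)
  expect_equal(nrow(vt), 22)
  m <- pearson_correlogram(vt)
  expect_gt(m["efficiency_sd", "mean_glucose_sd"], 0.6)
})

test_that("Welch's F handles hand-checkable cases", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  res <- welch_f(g)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)

  withr::with_seed(120, {
    two <- list(a = rnorm(12, 0, 1), b = rnorm(8, 1, 3))
  })
  wf <- welch_f(two)
  tt <- t.test(two$a, two$b, var.equal = FALSE)
  expect_equal(wf$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(wf$df2, unname(tt$parameter), tolerance = 1e-9)
  expect_equal(wf$p, tt$p.value, tolerance = 1e-9)

  expect_error(welch_f(list(a = c(1, 2), b = c(3, 3))), "\\bb\\b")
  expect_error(welch_f(list(a = c(1, 2))), "two groups")
})

test_that("Welch's F agrees with the classical F under equal variances", {
  # exact for two equal-sized, equal-variance groups (the standard errors
  # coincide, so the statistics do)
  base <- c(-2, -1, 0, 1, 2, 3)
  g2 <- list(a = base, b = base + 2)
  wf2 <- welch_f(g2)
  cl2 <- oneway.test(c(g2$a, g2$b) ~ factor(rep(c("a", "b"), each = 6)),
                     var.equal = TRUE)
  expect_equal(wf2$F, unname(cl2$statistic), tolerance = 1e-9)

  # for k > 2 Welch's small-sample denominator correction keeps F slightly
  # below the classical value, vanishing as n grows
  big <- seq(-1, 1, length.out = 400)
  g3 <- list(a = big, b = big + 0.1, c = big + 0.25)
  wf3 <- welch_f(g3)
  cl3 <- oneway.test(unlist(g3) ~ factor(rep(names(g3), each = 400)),
                     var.equal = TRUE)
  expect_lt(wf3$F, unname(cl3$statistic))
  expect_equal(wf3$F, unname(cl3$statistic), tolerance = 1e-2)
})

test_that("Bonferroni pairwise tests adjust by the number of pairs", {
  withr::with_seed(121, {
    g2 <- list(a = rnorm(10), b = rnorm(10))
    g4 <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20), d = rnorm(20, 3))
  })
  p2 <- pairwise_bonferroni(g2)
  expect_equal(nrow(p2), 1)
  expect_equal(p2$p_adj, p2$p)  # k = 2: factor 1

  p4 <- pairwise_bonferroni(g4)
  expect_equal(nrow(p4), 6)     # C(4, 2)
  expect_equal(p4$p_adj, pmin(1, 6 * p4$p))
  expect_true(all(p4$p_adj >= p4$p))
  expect_true(all(p4$p_adj <= 1))
  # only the three pairs involving the shifted group are significant
  hit <- p4$group1 == "d" | p4$group2 == "d"
  expect_true(all(p4$significant[hit]))
  expect_false(any(p4$significant[!hit]))
})

test_that("cluster comparisons wire metrics, clusters and tests together", {
  tabs <- make_cohort_tables(seed = 122)
  nights <- lapply(seq_len(nrow(tabs$daily)), function(i) NULL)
  ids <- paste(tabs$daily$participant_id, format(tabs$daily$night_date),
               sep = "_")
  withr::with_seed(123, {
    assignments <- setNames(sample(1:2, length(ids), TRUE), ids)
  })
  cmp <- compare_clusters(tabs$daily, assignments, "tir")
  expect_s3_class(cmp$pairwise, "data.frame")
  expect_equal(length(cmp$group_means), 2)
  expect_true(cmp$welch$p >= 0 && cmp$welch$p <= 1)
})
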