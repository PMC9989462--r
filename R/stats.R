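#' Participant-level variable table
#'
#' Assembles the one-row-per-participant table behind the correlogram: means
#' and SDs over nights of the sleep variables (efficiency, sleep time, WASO,
#' awakenings, good/poor counts) joined with means and SDs over days of the
#' glycemic variables (mean glucose, SD, CV, TIR, time in hypo/hyper). The
#' `efficiency_sd` and `mean_glucose_sd` columns are the night-to-night
#' variability measures whose association the study design targets.
#' Participants with fewer than `min_nights` nights cannot contribute SDs
#' and are dropped.
#'
#' @param sleep_agg Result of [aggregate_sleep()].
#' @param glyc_agg Result of [aggregate_glycemia()].
#' @param min_nights Minimum nights for a row to be retained (default 2).
#' @return Data frame, one row per retained participant.
#' @export
build_variable_table <- function(sleep_agg, glyc_agg, min_nights = 2) {
  s <- sleep_agg$participants
  g <- glyc_agg$participants
  tab <- merge(s, g, by = "participant_id",
               suffixes = c("_sleep", "_glyc"))
  tab <- tab[tab$nights_sleep >= min_nights & tab$nights_glyc >= min_nights, ]
  tab$nights <- tab$nights_sleep
  tab$nights_sleep <- tab$nights_glyc <- NULL
  rownames(tab) <- NULL
  tab
}

#' Pearson correlation matrix
#'
#' Pairwise Pearson correlations over the numeric columns of a
#' participant-level table; symmetric with unit diagonal. Zero-variance
#' columns get `NA` in their row and column rather than propagating an
#' error.
#'
#' @param tab Data frame (non-numeric columns are ignored); needs >= 3 rows.
#' @return Correlation matrix.
#' @export
pearson_correlogram <- function(tab) {
  num <- tab[, vapply(tab, is.numeric, logical(1)), drop = FALSE]
  if (nrow(num) < 3) stop("need at least 3 participants for correlations")
  m <- suppressWarnings(stats::cor(as.matrix(num),
                                   use = "pairwise.complete.obs"))
  zero_var <- vapply(num, function(x) stats::sd(x, na.rm = TRUE) == 0,
                     logical(1))
  m[zero_var, ] <- NA
  m[, zero_var] <- NA
  diag(m)[!zero_var] <- 1
  m
}

#' Welch's heteroscedastic one-way F-test
#'
#' Compares group means without assuming equal variances, with
#' Welch-Satterthwaite denominator degrees of freedom -- the appropriate
#' omnibus test when cluster sizes and variances differ. Wraps
#' `stats::oneway.test(var.equal = FALSE)`.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each with >= 2
#'   values and positive variance; a degenerate group is an error naming
#'   it).
#' @return List of class `welch_result`: `F`, `df1`, `df2`, `p`.
#' @export
welch_f <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups")
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  for (nm in names(groups)) {
    x <- groups[[nm]][!is.na(groups[[nm]])]
    if (length(x) < 2 || stats::var(x) <= 0) {
      stop("degenerate group (need >= 2 values and positive variance): ", nm)
    }
  }
  values <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups), lengths(groups)))
  ht <- stats::oneway.test(values ~ grp, var.equal = FALSE)
  structure(
    list(F = unname(ht$statistic), df1 = unname(ht$parameter[1]),
         df2 = unname(ht$parameter[2]), p = ht$p.value),
    class = "welch_result"
  )
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch F(%.1f, %.1f) = %.3f, p = %.4g\n",
              x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' Pairwise Welch t-tests with Bonferroni correction
#'
#' All C(k, 2) two-sample Welch t-tests between groups, with the adjusted
#' p-value `min(1, C(k,2) * p)`. With two groups the adjustment factor is 1
#' and the squared t statistic equals the Welch F.
#'
#' @param groups Named list of numeric vectors.
#' @param alpha Significance level for the `significant` flag (default
#'   0.05).
#' @return Data frame (group1, group2, statistic, df, p, p_adj,
#'   significant).
#' @export
pairwise_bonferroni <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("need at least two groups")
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  nms <- names(groups)
  pairs <- utils::combn(nms, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    ht <- stats::t.test(groups[[a]], groups[[b]], var.equal = FALSE)
    data.frame(group1 = a, group2 = b,
               statistic = unname(ht$statistic),
               df = unname(ht$parameter),
               p = ht$p.value,
               p_adj = min(1, m * ht$p.value))
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_adj < alpha
  out
}

#' Compare a glycemic variable across clusters
#'
#' Splits a per-day metric by cluster assignment and runs [welch_f()] plus
#' [pairwise_bonferroni()].
#'
#' @param day_summaries Data frame of [summarize_day()] rows.
#' @param assignments Named assignment vector from [kmeans_fit()] (names are
#'   night ids).
#' @param metric Column of `day_summaries` to compare (e.g. `"tir"`).
#' @param alpha Significance level.
#' @return List with `metric`, `welch`, `pairwise`, `group_means`.
#' @export
compare_clusters <- function(day_summaries, assignments, metric,
                             alpha = 0.05) {
  ids <- night_id(day_summaries$participant_id, day_summaries$night_date)
  cl <- assignments[ids]
  ok <- !is.na(cl) & !is.na(day_summaries[[metric]])
  groups <- split(day_summaries[[metric]][ok],
                  paste0("cluster", cl[ok]))
  list(
    metric = metric,
    welch = welch_f(groups),
    pairwise = pairwise_bonferroni(groups, alpha = alpha),
    group_means = vapply(groups, mean, 0)
  )
}
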