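#' Run configuration for the end-to-end pipeline
#'
#' @param sim A [sim_params()] describing the synthetic cohort to generate
#'   (the seed inside it governs every stochastic stage except clustering
#'   restarts, which use `cluster_seed`).
#' @param window Glycemia window for per-day summaries: `"night"` or
#'   `"day"`.
#' @param k Number of sleep clusters.
#' @param encoding Night encoding mode, `"transitions"` or `"sequence"`.
#' @param cluster_seed Seed for k-means restarts (defaults to the simulation
#'   seed).
#' @param sax A [sax_config()].
#' @param alpha Significance level for cluster comparisons.
#' @param metrics Glycemic variables compared across clusters.
#' @param out_dir Output directory for stage CSVs and the manifest; `NULL`
#'   keeps everything in memory.
#' @return Object of class `run_config`.
#' @export
run_config <- function(sim = sim_params(), window = "night", k = 4,
                       encoding = "transitions", cluster_seed = NULL,
                       sax = sax_config(), alpha = 0.05,
                       metrics = c("tir", "mean_glucose", "sd", "cv"),
                       out_dir = NULL) {
  stopifnot(inherits(sim, "sim_params"), inherits(sax, "sax_config"))
  if (is.null(sim$seed)) stop("a seed is required to run the pipeline")
  structure(
    list(sim = sim, window = match.arg(window, c("night", "day")), k = k,
         encoding = match.arg(encoding, c("transitions", "sequence")),
         cluster_seed = as.integer(cluster_seed %||% sim$seed),
         sax = sax, alpha = alpha, metrics = metrics, out_dir = out_dir),
    class = "run_config"
  )
}

write_stage_csv <- function(df, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  path <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline end to end
#'
#' Orchestrates every stage on a synthetic cohort: generate paired
#' sleep/glucose data, write and re-read it in the device dialects (so the
#' ingest path is exercised), synchronize each night with its day,
#' apply the day filters, compute per-night sleep and per-day glycemia
#' summaries and their cohort aggregations, encode and cluster the nights,
#' average glucose by cluster, mine cluster-specific motifs, and compare the
#' glycemic variables across clusters. Record counts are conserved or
#' explicitly accounted for at every filter, and the returned manifest
#' (seed, counts, stage checksums) is bit-identical across runs with the
#' same configuration.
#'
#' @param config A [run_config()].
#' @return List of class `pipeline_result` with elements `cohort`,
#'   `records`, `discarded`, `sleep_nightly`, `sleep_agg`, `glyc_daily`,
#'   `glyc_agg`, `clusters`, `profiles`, `entropy_ranking`, `spec`,
#'   `variable_table`, `correlogram`, `comparisons`, `manifest`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir <- config$out_dir
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- simulate_cohort(config$sim)
  raw_dir <- file.path(dir %||% tempfile("noctiglyc_raw_"), "raw")
  write_cohort(cohort, raw_dir)

  # ingest the files back (round-trips the device dialects)
  pids <- cohort$participants$participant_id
  traces <- lapply(pids, function(p) {
    read_cgm_csv(file.path(raw_dir, paste0(p, "_cgm.csv")))
  })
  names(traces) <- pids
  nights <- unlist(lapply(pids, function(p) {
    read_sleep_json(file.path(raw_dir, paste0(p, "_sleep.json")),
                    participant_id = p)
  }), recursive = FALSE)

  records <- lapply(nights, function(n) synchronize(traces[[n$participant_id]], n))
  flt <- filter_days(records)
  kept <- flt$kept

  sleep_nightly <- do.call(rbind, lapply(nights, night_summary))
  sleep_agg <- aggregate_sleep(sleep_nightly)

  glyc_rows <- vector("list", length(kept))
  prev_of <- function(i) {
    if (i == 1) return(NULL)
    p <- kept[[i - 1]]
    same <- p$participant_id == kept[[i]]$participant_id &&
      as.numeric(kept[[i]]$night$night_date - p$night$night_date) == 1
    if (same) p else NULL
  }
  for (i in seq_along(kept)) {
    glyc_rows[[i]] <- summarize_day(kept[[i]], window = config$window,
                                    prev_record = prev_of(i))
  }
  glyc_daily <- do.call(rbind, glyc_rows)
  glyc_agg <- aggregate_glycemia(glyc_daily)

  kept_nights <- lapply(kept, function(r) r$night)
  enc <- encode_nights(kept_nights, mode = config$encoding,
                       n_slots = config$sim$night_slots)
  clusters <- kmeans_fit(enc, config$k, seed = config$cluster_seed)
  profiles <- cluster_glucose_profiles(clusters, kept)
  entropy_ranking <- rank_clusters_by_entropy(clusters, kept_nights)
  spec <- specificity(build_corpora(clusters, kept, config$sax))

  variable_table <- build_variable_table(sleep_agg, glyc_agg)
  correlogram <- pearson_correlogram(variable_table)
  comparisons <- lapply(config$metrics, function(m) {
    compare_clusters(glyc_daily, clusters$assignments, m,
                     alpha = config$alpha)
  })
  names(comparisons) <- config$metrics

  stage_dir <- dir %||% tempfile("noctiglyc_stages_")
  if (is.null(dir)) dir.create(stage_dir, recursive = TRUE)
  stages <- list(
    sleep_nightly = sleep_nightly,
    glycemia_daily = glyc_daily,
    cluster_assignments = data.frame(night = names(clusters$assignments),
                                     cluster = unname(clusters$assignments)),
    cluster_profiles = as.data.frame(profiles),
    variable_table = variable_table
  )
  stage_files <- vapply(names(stages), function(nm) {
    write_stage_csv(stages[[nm]], stage_dir, nm)
  }, "")

  manifest <- list(
    package_version = as.character(utils::packageVersion("noctiglyc")),
    seed = config$sim$seed,
    cluster_seed = config$cluster_seed,
    window = config$window, k = config$k, encoding = config$encoding,
    counts = list(
      participants = length(pids),
      nights_simulated = length(nights),
      records_synchronized = length(records),
      days_kept = length(kept),
      days_discarded = nrow(flt$discarded),
      cluster_sizes = as.integer(clusters$sizes)
    ),
    checksums = stats::setNames(as.list(unname(tools::md5sum(stage_files))),
                                names(stages))
  )
  if (length(nights) != length(kept) + nrow(flt$discarded)) {
    stop("record counts not conserved across filtering")
  }
  if (!is.null(dir)) {
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  structure(
    list(cohort = cohort, records = records, discarded = flt$discarded,
         sleep_nightly = sleep_nightly, sleep_agg = sleep_agg,
         glyc_daily = glyc_daily, glyc_agg = glyc_agg,
         clusters = clusters, profiles = profiles,
         entropy_ranking = entropy_ranking, spec = spec,
         variable_table = variable_table, correlogram = correlogram,
         comparisons = comparisons, manifest = manifest),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest$counts
  cat(sprintf(
    paste0("<pipeline_result> %d participants, %d nights (%d kept, %d ",
           "discarded), k = %d clusters (sizes %s)\n"),
    m$participants, m$nights_simulated, m$days_kept, m$days_discarded,
    x$clusters$k, paste(m$cluster_sizes, collapse = "/")
  ))
  invisible(x)
}
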