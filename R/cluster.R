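#' Encode nights as fixed-length feature vectors
#'
#' Two encodings of a night's 15-minute state sequence are supported.
#' `"transitions"` (default): the flattened 4x4 matrix of adjacent
#' state-pair counts (16 features), which characterizes the night by how it
#' moves between stages and is robust to night-length differences.
#' `"sequence"`: the one-hot sequence of `n_slots` slots x 4 states
#' (`4 * n_slots` features); shorter nights are padded with wake at the
#' tail (recorded in attribute `"padded"`), longer nights are truncated with
#' a warning.
#'
#' @param nights List of [hypnogram()] objects.
#' @param mode `"transitions"` or `"sequence"`.
#' @param n_slots Fixed slot count for sequence mode (default 44).
#' @param slot_minutes Slot length in minutes.
#' @return Numeric matrix, one row per night (rownames are night ids),
#'   with attributes `"mode"` and, in sequence mode, `"padded"`.
#' @export
encode_nights <- function(nights, mode = c("transitions", "sequence"),
                          n_slots = 44, slot_minutes = 15) {
  mode <- match.arg(mode)
  ids <- vapply(nights, function(n) night_id(n$participant_id, n$night_date), "")
  seqs <- lapply(nights, hypnogram_slots, slot_minutes = slot_minutes)
  if (mode == "transitions") {
    feat_names <- as.vector(outer(SLEEP_STATES, SLEEP_STATES,
                                  function(a, b) paste(a, b, sep = "->")))
    enc <- t(vapply(seqs, function(s) {
      tab <- table(factor(s[-length(s)], levels = SLEEP_STATES),
                   factor(s[-1], levels = SLEEP_STATES))
      as.vector(tab)
    }, numeric(16)))
    colnames(enc) <- feat_names
  } else {
    padded <- logical(length(seqs))
    enc <- t(vapply(seq_along(seqs), function(i) {
      s <- seqs[[i]]
      if (length(s) > n_slots) {
        warning("night ", ids[i], " longer than ", n_slots,
                " slots; truncated")
        s <- s[seq_len(n_slots)]
      } else if (length(s) < n_slots) {
        padded[i] <<- TRUE
        s <- c(s, rep("wake", n_slots - length(s)))
      }
      as.vector(vapply(s, function(st) as.numeric(SLEEP_STATES == st),
                       numeric(4)))
    }, numeric(4 * n_slots)))
    colnames(enc) <- paste0(
      rep(paste0("slot", seq_len(n_slots)), each = 4), "_",
      rep(SLEEP_STATES, n_slots)
    )
    attr(enc, "padded") <- padded
  }
  rownames(enc) <- ids
  attr(enc, "mode") <- mode
  enc
}

#' Group night encodings with k-means
#'
#' Euclidean k-means with multiple random restarts; the best restart by
#' total within-cluster sum of squares is kept. Deterministic given `seed`.
#'
#' @param encodings Matrix from [encode_nights()].
#' @param k Number of clusters (1 <= k <= number of nights).
#' @param seed Integer seed (mandatory; clustering is stochastic).
#' @param n_restarts Number of random restarts (default 10).
#' @param iter_max Maximum Lloyd iterations per restart.
#' @return Object of class `cluster_result`: `k`, `assignments` (named
#'   integer vector), `centroids`, `sizes`, `inertia`, `encoding_mode`.
#' @export
kmeans_fit <- function(encodings, k, seed, n_restarts = 10, iter_max = 300) {
  n <- nrow(encodings)
  if (k < 1 || k > n) stop("k must be between 1 and the number of nights")
  if (missing(seed) || is.null(seed)) stop("a seed is required for clustering")
  km <- withr::with_seed(as.integer(seed), {
    stats::kmeans(encodings, centers = k, nstart = n_restarts,
                  iter.max = iter_max)
  })
  assignments <- km$cluster
  names(assignments) <- rownames(encodings)
  structure(
    list(
      k = k,
      assignments = assignments,
      centroids = km$centers,
      sizes = as.integer(km$size),
      inertia = km$tot.withinss,
      encoding_mode = attr(encodings, "mode") %||% "unknown"
    ),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d (%s encoding), sizes: %s, inertia %.2f\n",
              x$k, x$encoding_mode, paste(x$sizes, collapse = "/"),
              x$inertia))
  invisible(x)
}

#' Per-cluster average 24-hour glucose profiles
#'
#' Bin-wise mean of the member days' 96-slot glucose grids for each cluster;
#' grid slots missing on some members are averaged over the available ones.
#'
#' @param result A [kmeans_fit()] result.
#' @param day_records List of `day_record`s whose night ids cover the
#'   clustered nights.
#' @return Numeric matrix `k x 96` (rownames `cluster1..k`), attribute
#'   `"minutes_of_day"` giving each bin's clock time.
#' @export
cluster_glucose_profiles <- function(result, day_records) {
  ids <- vapply(day_records,
                function(r) night_id(r$participant_id, r$night$night_date), "")
  profiles <- matrix(NA_real_, nrow = result$k,
                     ncol = nrow(day_records[[1]]$day_glucose),
                     dimnames = list(paste0("cluster", seq_len(result$k)), NULL))
  for (cl in seq_len(result$k)) {
    members <- names(result$assignments)[result$assignments == cl]
    idx <- match(members, ids)
    idx <- idx[!is.na(idx)]
    if (!length(idx)) stop("cluster ", cl, " has no day records")
    mat <- do.call(rbind, lapply(day_records[idx],
                                 function(r) r$day_glucose$glucose))
    profiles[cl, ] <- colMeans(mat, na.rm = TRUE)
  }
  attr(profiles, "minutes_of_day") <-
    minutes_of_day(day_records[[1]]$day_glucose$time)
  profiles
}

#' Rank clusters by mean sleep-sequence entropy
#'
#' Orders clusters from most to least disordered sleep, by the mean Shannon
#' entropy of their member nights.
#'
#' @param result A [kmeans_fit()] result.
#' @param nights List of [hypnogram()]s covering the clustered nights.
#' @param mode Entropy mode, see [state_entropy()].
#' @return Data frame (cluster, n, mean_entropy) sorted descending.
#' @export
rank_clusters_by_entropy <- function(result, nights,
                                     mode = "transitions") {
  ids <- vapply(nights, function(n) night_id(n$participant_id, n$night_date), "")
  ent <- vapply(nights, state_entropy, 0, mode = mode)
  rows <- lapply(seq_len(result$k), function(cl) {
    members <- names(result$assignments)[result$assignments == cl]
    idx <- match(members, ids)
    idx <- idx[!is.na(idx)]
    data.frame(cluster = cl, n = length(idx),
               mean_entropy = mean(ent[idx]))
  })
  out <- do.call(rbind, rows)
  out[order(-out$mean_entropy), ]
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions (up to relabeling), ~0 for independent ones. Used to
#' score recovery of planted archetypes.
#'
#' @param a,b Label vectors of equal length.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Mean silhouette width of a clustering
#'
#' Standard silhouette score on Euclidean distances, used for the k sweep:
#' for each point, (b - a) / max(a, b) with a the mean distance to its own
#' cluster and b the smallest mean distance to another cluster.
#'
#' @param encodings Feature matrix.
#' @param assignments Integer cluster labels.
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
silhouette_width <- function(encodings, assignments) {
  d <- as.matrix(stats::dist(encodings))
  n <- nrow(d)
  ks <- sort(unique(assignments))
  if (length(ks) < 2) stop("silhouette needs at least two clusters")
  s <- vapply(seq_len(n), function(i) {
    own <- assignments == assignments[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(d[i, own]) else 0
    b <- min(vapply(setdiff(ks, assignments[i]),
                    function(cl) mean(d[i, assignments == cl]), 0))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, 0)
  mean(s)
}

#' Sweep k for k-means and score by silhouette
#'
#' Fits [kmeans_fit()] for each candidate k and reports inertia and mean
#' silhouette width, the package's documented device for choosing k.
#'
#' @param encodings Feature matrix.
#' @param ks Candidate cluster counts (default 2:6).
#' @param seed Integer seed.
#' @param ... Passed to [kmeans_fit()].
#' @return Data frame (k, inertia, silhouette).
#' @export
sweep_k <- function(encodings, ks = 2:6, seed, ...) {
  rows <- lapply(ks, function(k) {
    fit <- kmeans_fit(encodings, k, seed = seed, ...)
    data.frame(k = k, inertia = fit$inertia,
               silhouette = silhouette_width(encodings, fit$assignments))
  })
  do.call(rbind, rows)
}
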