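#' Symbolic-representation configuration
#'
#' Parameters of the PAA/SAX word extraction applied to cluster-average
#' glucose curves: z-normalize the series, average blocks of `paa_factor`
#' samples (96-sample day -> 24 averaged points with the default factor 4),
#' discretize with `alphabet_size` equiprobable Gaussian symbols, and slide
#' windows of `word_length` symbols with stride `window_step` to form words.
#'
#' @param paa_factor Samples averaged per PAA point (default 4).
#' @param word_length Symbols per word (default 12).
#' @param alphabet_size SAX alphabet size (default 7; 2-20).
#' @param znormalize Whether to z-normalize before PAA (default TRUE).
#' @param window_step Word-window stride in symbols (default 1; set to
#'   `word_length` for non-overlapping words).
#' @return Object of class `sax_config`.
#' @export
sax_config <- function(paa_factor = 4, word_length = 12, alphabet_size = 7,
                       znormalize = TRUE, window_step = 1) {
  stopifnot(paa_factor >= 1, word_length >= 1, window_step >= 1,
            alphabet_size >= 2, alphabet_size <= 20)
  structure(
    list(paa_factor = paa_factor, word_length = word_length,
         alphabet_size = alphabet_size, znormalize = znormalize,
         window_step = window_step),
    class = "sax_config"
  )
}

#' Z-normalize a series
#'
#' Subtract the mean and divide by the (sample) standard deviation. A
#' constant series maps to all zeros by convention.
#'
#' @param x Numeric vector.
#' @return Numeric vector with mean 0 and SD 1 (or all zeros).
#' @export
znorm <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Piecewise aggregate approximation
#'
#' Reduce a series to block means of `factor` consecutive values. When the
#' length is not divisible by `factor` the series is padded with its last
#' value (recorded in attribute `"padded"`).
#'
#' @param x Numeric vector.
#' @param factor Block size (>= 1).
#' @return Numeric vector of block means.
#' @export
paa <- function(x, factor) {
  stopifnot(factor >= 1)
  padded <- length(x) %% factor != 0
  if (padded) x <- c(x, rep(x[length(x)], factor - length(x) %% factor))
  out <- colMeans(matrix(x, nrow = factor))
  attr(out, "padded") <- padded
  out
}

#' SAX symbolization
#'
#' Assign each (z-normalized) value a letter by the standard-normal
#' equiprobable breakpoints: an alphabet of size `a` uses the `a - 1`
#' Gaussian quantiles at `1/a, 2/a, ...` so that Gaussian inputs use all
#' symbols equally often. Symbols are `letters[1..a]` in increasing value
#' order.
#'
#' @param x Numeric vector (z-normalized upstream).
#' @param alphabet_size Alphabet size (2-20).
#' @return Character vector of symbols, attribute `"breakpoints"`.
#' @export
sax <- function(x, alphabet_size = 7) {
  stopifnot(alphabet_size >= 2, alphabet_size <= 20)
  bp <- stats::qnorm(seq_len(alphabet_size - 1) / alphabet_size)
  sym <- letters[findInterval(x, bp) + 1]
  attr(sym, "breakpoints") <- bp
  sym
}

#' Sliding-window bag of words
#'
#' Group a symbol sequence into words of `word_length` symbols, sliding by
#' `step`. The start position (in symbols) of each word is kept in attribute
#' `"starts"` so that word scores can be mapped back to time bins.
#'
#' @param symbols Character vector of SAX symbols.
#' @param word_length Symbols per word.
#' @param step Stride between word starts.
#' @return Character vector of words (empty, with a warning, when the input
#'   is shorter than `word_length`).
#' @export
bag_of_words <- function(symbols, word_length = 12, step = 1) {
  n <- length(symbols)
  if (n < word_length) {
    warning("series of ", n, " symbols is shorter than word_length ",
            word_length, "; empty bag")
    out <- character(0)
    attr(out, "starts") <- integer(0)
    return(out)
  }
  starts <- seq(1, n - word_length + 1, by = step)
  s <- paste(symbols, collapse = "")
  words <- substring(s, starts, starts + word_length - 1)
  attr(words, "starts") <- starts
  words
}

#' Extract SAX words from one glucose series
#'
#' Full symbolic pipeline for a single day curve: z-normalize (optional),
#' PAA, SAX, bag of words.
#'
#' @param glucose Numeric vector (e.g. a 96-sample day grid); `NA`s are
#'   linearly interpolated, and a series with fewer than 2 observed values
#'   yields an empty bag.
#' @param config A [sax_config()].
#' @return Character vector of words with attribute `"starts"` (PAA-bin
#'   start positions).
#' @export
sax_words <- function(glucose, config = sax_config()) {
  g <- glucose
  if (anyNA(g)) {
    obs <- which(!is.na(g))
    if (length(obs) < 2) {
      out <- character(0); attr(out, "starts") <- integer(0)
      return(out)
    }
    g <- stats::approx(obs, g[obs], xout = seq_along(g), rule = 2)$y
  }
  if (config$znormalize) g <- znorm(g)
  reduced <- paa(g, config$paa_factor)
  syms <- sax(as.numeric(reduced), config$alphabet_size)
  bag_of_words(syms, config$word_length, config$window_step)
}

#' TF-IDF weighting of per-cluster word corpora
#'
#' Clusters act as documents: `tf(w, c)` is the count of word `w` in cluster
#' `c` divided by the cluster's total word count, `idf(w) = ln(K / df(w))`
#' with `df(w)` the number of clusters containing `w`, and the weight is
#' `tf * idf`. A word present in every cluster gets weight 0 everywhere; a
#' word private to one of K clusters gets `idf = ln K`.
#'
#' @param corpora Named list (one element per cluster) of word vectors
#'   (multisets; repeats count).
#' @return Object of class `word_corpus`: `vocabulary`, `counts` (K x V),
#'   `tf`, `idf`, `weights`.
#' @export
tfidf <- function(corpora) {
  if (length(corpora) < 2) stop("TF-IDF needs at least 2 clusters")
  empty <- vapply(corpora, function(x) length(x) == 0, logical(1))
  if (any(empty)) {
    stop("empty corpus for cluster: ",
         paste(names(corpora)[empty], collapse = ", "))
  }
  vocab <- sort(unique(unlist(corpora, use.names = FALSE)))
  counts <- t(vapply(corpora, function(w) {
    as.numeric(table(factor(w, levels = vocab)))
  }, numeric(length(vocab))))
  dimnames(counts) <- list(names(corpora), vocab)
  tf <- counts / rowSums(counts)
  df <- colSums(counts > 0)
  idf <- log(nrow(counts) / df)
  structure(
    list(vocabulary = vocab, counts = counts, tf = tf, idf = idf,
         weights = sweep(tf, 2, idf, `*`)),
    class = "word_corpus"
  )
}

#' Build positional word corpora per cluster
#'
#' Runs [sax_words()] on each clustered day's glucose grid and groups the
#' resulting (word, start-position) occurrences by cluster, the input both
#' [tfidf()] and [specificity()] need.
#'
#' @param result A [kmeans_fit()] result.
#' @param day_records List of `day_record`s.
#' @param config A [sax_config()].
#' @return Named list per cluster of data frames (word, start), with
#'   attributes `"n_positions"` (word-start slots per day) and `"config"`.
#' @export
build_corpora <- function(result, day_records, config = sax_config()) {
  ids <- vapply(day_records,
                function(r) night_id(r$participant_id, r$night$night_date), "")
  out <- lapply(seq_len(result$k), function(cl) {
    members <- names(result$assignments)[result$assignments == cl]
    idx <- match(members, ids)
    idx <- idx[!is.na(idx)]
    occ <- lapply(day_records[idx], function(r) {
      w <- sax_words(r$day_glucose$glucose, config)
      data.frame(word = as.character(w),
                 start = attr(w, "starts") %||% integer(0))
    })
    do.call(rbind, occ)
  })
  names(out) <- paste0("cluster", seq_len(result$k))
  n_series <- length(day_records[[1]]$day_glucose$glucose)
  n_paa <- ceiling(n_series / config$paa_factor)
  attr(out, "n_positions") <- max(1, n_paa - config$word_length + 1)
  attr(out, "n_paa") <- n_paa
  attr(out, "config") <- config
  out
}

#' Word- and bin-level cluster specificity
#'
#' Scores how specific each word -- and, through the words covering it, each
#' time bin of the cluster-average curve -- is to its cluster. For word `w`
#' and cluster `c` the operands of the cosine are the word's positional
#' occurrence profiles (counts of `w` starting at each window position): the
#' specificity is `1 - max` cosine similarity against the same word's
#' profile in any other cluster, with the convention that cosine against an
#' all-zero profile is 0. A word occurring only in one cluster therefore
#' scores 1 there; identical corpora in all clusters score 0 everywhere. The
#' per-bin score of a cluster is the mean specificity over the word
#' occurrences whose window covers the bin (bins covered by no word carry
#' `NA`).
#'
#' @param corpora Positional corpora from [build_corpora()].
#' @return List of class `specificity_profile`: `word_spec` (K x V matrix,
#'   `NA` where a word is absent from a cluster), `bin_spec` (K x n PAA
#'   bins), `bin_spec_series` (K x original-series length), `corpus` (the
#'   [tfidf()] object).
#' @export
specificity <- function(corpora) {
  cfg <- attr(corpora, "config")
  n_pos <- attr(corpora, "n_positions")
  n_paa <- attr(corpora, "n_paa")
  corpus <- tfidf(lapply(corpora, function(d) d$word))
  vocab <- corpus$vocabulary
  K <- length(corpora)
  # positional profile array: word x cluster x position
  prof <- lapply(seq_len(K), function(cl) {
    d <- corpora[[cl]]
    m <- matrix(0, nrow = length(vocab), ncol = n_pos,
                dimnames = list(vocab, NULL))
    if (nrow(d)) {
      tab <- table(factor(d$word, levels = vocab), factor(d$start, levels = 1:n_pos))
      m <- m + as.matrix(tab)
    }
    m
  })
  word_spec <- matrix(NA_real_, nrow = K, ncol = length(vocab),
                      dimnames = list(names(corpora), vocab))
  for (cl in seq_len(K)) {
    for (w in seq_along(vocab)) {
      own <- prof[[cl]][w, ]
      if (sum(own) == 0) next
      sims <- vapply(setdiff(seq_len(K), cl),
                     function(o) cosine_sim(own, prof[[o]][w, ]), 0)
      word_spec[cl, w] <- 1 - max(sims)
    }
  }
  wl <- cfg$word_length
  bin_spec <- matrix(NA_real_, nrow = K, ncol = n_paa,
                     dimnames = list(names(corpora), NULL))
  for (cl in seq_len(K)) {
    d <- corpora[[cl]]
    if (!nrow(d)) next
    sc <- word_spec[cl, match(d$word, vocab)]
    for (b in seq_len(n_paa)) {
      covers <- d$start <= b & b <= d$start + wl - 1
      if (any(covers)) bin_spec[cl, b] <- mean(sc[covers])
    }
  }
  bin_series <- bin_spec[, rep(seq_len(n_paa), each = cfg$paa_factor),
                         drop = FALSE]
  structure(
    list(word_spec = word_spec, bin_spec = bin_spec,
         bin_spec_series = bin_series, corpus = corpus),
    class = "specificity_profile"
  )
}

#' Cluster-level cosine similarity of TF-IDF vectors
#'
#' The coarser reading of motif similarity: one cosine per cluster pair,
#' computed between whole-cluster TF-IDF weight vectors.
#'
#' @param corpus A [tfidf()] result.
#' @return Symmetric K x K similarity matrix with unit diagonal.
#' @export
cluster_similarity <- function(corpus) {
  w <- corpus$weights
  K <- nrow(w)
  out <- diag(1, K)
  dimnames(out) <- list(rownames(w), rownames(w))
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      out[i, j] <- out[j, i] <- cosine_sim(w[i, ], w[j, ])
    }
  }
  out
}
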