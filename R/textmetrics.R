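#' Word-level edit distance with operation counts
#'
#' Levenshtein distance between two word sequences by dynamic programming,
#' with the minimizing numbers of substitutions, insertions and deletions
#' recovered by backtrace (insertions turn the reference into the decoded
#' sequence; ties prefer substitution, then deletion).
#'
#' @param reference,decoded character vectors of words, or single strings
#'   split on whitespace.
#' @return Named numeric vector `c(substitutions, insertions, deletions,
#'   distance)`.
#' @export
word_edit_ops <- function(reference, decoded) {
  r <- tokenize_words(reference)
  h <- tokenize_words(decoded)
  n <- length(r); m <- length(h)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  if (n && m) {
    for (i in seq_len(n)) {
      for (j in seq_len(m)) {
        sub_cost <- d[i, j] + (r[i] != h[j])
        d[i + 1, j + 1] <- min(sub_cost, d[i, j + 1] + 1L, d[i + 1, j] + 1L)
      }
    }
  }
  subs <- ins <- del <- 0L
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && d[i + 1, j + 1] == d[i, j] + (r[i] != h[j])) {
      subs <- subs + (r[i] != h[j])
      i <- i - 1; j <- j - 1
    } else if (i > 0 && d[i + 1, j + 1] == d[i, j + 1] + 1L) {
      del <- del + 1L
      i <- i - 1
    } else {
      ins <- ins + 1L
      j <- j - 1
    }
  }
  c(substitutions = subs, insertions = ins, deletions = del,
    distance = d[n + 1, m + 1])
}

tokenize_words <- function(x) {
  if (length(x) == 1L && (is.character(x))) {
    w <- strsplit(trimws(x), "\\s+")[[1]]
    w[nzchar(w)]
  } else {
    as.character(x)
  }
}

#' Aggregate word error rate with a bootstrap confidence interval
#'
#' The aggregate WER sums word-level edit errors over all sentence pairs
#' and divides by the total number of reference words, avoiding the
#' over-weighting of short sentences that sentence-level averaging would
#' cause. It can exceed 1 (100%) when errors outnumber reference words.
#' The confidence interval resamples sentence pairs with replacement and
#' recomputes the aggregate.
#'
#' @param reference,decoded character vectors of sentences (aligned).
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed integer seed.
#' @param alpha interval level (default 0.05).
#' @return An object of class `wer_report`: `wer` (proportion), `ci`,
#'   `per_sentence` (data frame of substitutions/insertions/deletions),
#'   `total_words`.
#' @export
aggregate_wer <- function(reference, decoded, n_boot = 10000, seed = 1,
                          alpha = 0.05) {
  if (!length(reference)) stop("no sentence pairs")
  if (length(reference) != length(decoded)) {
    stop("reference and decoded must be aligned")
  }
  ops <- t(vapply(seq_along(reference), function(i) {
    r <- tokenize_words(reference[[i]])
    if (!length(r)) stop(sprintf("empty reference sentence in pair %d", i))
    c(word_edit_ops(r, tokenize_words(decoded[[i]])), n_words = length(r))
  }, numeric(5)))
  per_sentence <- as.data.frame(ops)
  wer <- sum(per_sentence$distance) / sum(per_sentence$n_words)
  ci <- with_seed(seed, {
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(per_sentence), replace = TRUE)
      sum(per_sentence$distance[idx]) / sum(per_sentence$n_words[idx])
    }, numeric(1))
    unname(quantile(boots, c(alpha / 2, 1 - alpha / 2), type = 7))
  })
  structure(
    list(wer = wer, ci = ci, per_sentence = per_sentence,
         total_words = sum(per_sentence$n_words)),
    class = "wer_report")
}

#' @export
print.wer_report <- function(x, ...) {
  cat(sprintf("<wer_report> aggregate WER %.1f%% (95%% CI [%.1f%%, %.1f%%]) over %d reference words\n",
              100 * x$wer, 100 * x$ci[1], 100 * x$ci[2], x$total_words))
  invisible(x)
}

#' Permutation chance level for the aggregate word error rate
#'
#' Randomly permutes the pairing between reference and decoded sentences
#' and recomputes the aggregate WER for each shuffle, destroying any
#' decoded-to-target relationship while keeping both marginals. The
#' chance level is the 2.5th percentile of the shuffled distribution; a
#' true WER below it indicates a significant decoder-target relationship.
#' Note the chance level can itself exceed 100%.
#'
#' @param reference,decoded aligned sentence vectors (at least 2 pairs).
#' @param n_shuffles permutations (default 10000; 100 reproduces the
#'   cheaper variant used for online evaluation summaries).
#' @param seed integer seed.
#' @return List with `chance_lower_bound`, `shuffled_wer` (the full
#'   distribution).
#' @export
shuffled_chance_wer <- function(reference, decoded, n_shuffles = 10000,
                                seed = 1) {
  n <- length(reference)
  if (n < 2) stop("need at least 2 pairs to permute")
  # cache all cross-pair distances once; shuffles then only index
  ref_tok <- lapply(reference, tokenize_words)
  dec_tok <- lapply(decoded, tokenize_words)
  n_words <- vapply(ref_tok, length, integer(1))
  if (any(n_words == 0)) stop("empty reference sentence")
  dmat <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      dmat[i, j] <- word_edit_ops(ref_tok[[i]], dec_tok[[j]])[["distance"]]
    }
  }
  total <- sum(n_words)
  with_seed(seed, {
    shuffled <- vapply(seq_len(n_shuffles), function(s) {
      perm <- sample.int(n)
      sum(dmat[cbind(seq_len(n), perm)]) / total
    }, numeric(1))
    list(chance_lower_bound = unname(quantile(shuffled, 0.025, type = 7)),
         shuffled_wer = shuffled)
  })
}

#' DTW-aligned mean phoneme-logit correlation
#'
#' Aligns two multivariate logit time series (paired trials of the same
#' sentence spoken at different rates) by dynamic time warping with the
#' symmetric2 step pattern and a slanted-band window of half-width
#' `band_ms`, then computes the Pearson correlation of the warped series
#' for each of the 39 phoneme dimensions (the final silence dimension is
#' excluded) and averages them. Zero-variance dimensions are skipped with
#' a warning.
#'
#' @param a,b matrices `bins x 40` with attribute `bin_ms` (default 80).
#' @param band_ms slanted-band half-width in ms (default 100).
#' @param n_phoneme number of leading phoneme dimensions to correlate
#'   (default `ncol(a) - 1`).
#' @return Scalar mean correlation.
#' @export
dtw_logit_correlation <- function(a, b, band_ms = 100,
                                  n_phoneme = ncol(a) - 1) {
  bin_ms <- attr(a, "bin_ms")
  if (is.null(bin_ms)) bin_ms <- 80
  if (band_ms < bin_ms) stop("band_ms must be at least one bin")
  al <- dtw_align(a, b, band_bins = band_ms / bin_ms)
  wa <- a[al$index_a, seq_len(n_phoneme), drop = FALSE]
  wb <- b[al$index_b, seq_len(n_phoneme), drop = FALSE]
  sds_a <- apply(wa, 2, sd)
  sds_b <- apply(wb, 2, sd)
  ok <- sds_a > 0 & sds_b > 0
  if (!all(ok)) {
    warning(sprintf("%d zero-variance dimension(s) skipped", sum(!ok)),
            call. = FALSE)
  }
  if (!any(ok)) return(NaN)
  mean(vapply(which(ok), function(k) cor(wa[, k], wb[, k]), numeric(1)))
}
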