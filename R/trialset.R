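#' Trial-structured neural feature container
#'
#' A `trial_set` holds binned neural features for a session as a
#' `trials x bins x features` array together with per-trial word, behavior
#' and block labels, the go-cue bin, and the block schedule. It is the
#' common currency between the session generator, the preprocessing steps
#' and the decoders.
#'
#' @param features numeric array `trials x bins x features`, nonnegative.
#' @param bin_ms bin width in milliseconds (10 or 20 in typical recordings).
#' @param word,behavior,block character vectors of per-trial labels, each of
#'   length `trials`.
#' @param go_bin integer vector (length `trials` or 1, recycled): index of
#'   the first go-epoch bin for each trial.
#' @param schedule `"blocked"` (behaviors in separate blocks) or
#'   `"interleaved"` (behaviors mixed within blocks).
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(features, bin_ms, word, behavior, block, go_bin,
                      schedule = c("blocked", "interleaved")) {
  schedule <- match.arg(schedule)
  stopifnot(is.array(features), length(dim(features)) == 3L)
  n <- dim(features)[1L]
  if (length(go_bin) == 1L) go_bin <- rep.int(go_bin, n)
  if (length(word) != n || length(behavior) != n || length(block) != n ||
      length(go_bin) != n) {
    stop("labels and go_bin must match the trial axis of `features`")
  }
  if (any(go_bin < 1L | go_bin > dim(features)[2L])) {
    stop("go_bin outside the recorded bin range")
  }
  if (!bin_ms %in% c(10, 20)) {
    stop("bin_ms must be 10 or 20")
  }
  structure(
    list(features = features, bin_ms = bin_ms,
         word = as.character(word), behavior = as.character(behavior),
         block = as.character(block), go_bin = as.integer(go_bin),
         schedule = schedule),
    class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$features)
  cat(sprintf(
    "<trial_set> %d trials x %d bins x %d features (%d ms bins, %s)\n",
    d[1], d[2], d[3], x$bin_ms, x$schedule))
  cat(sprintf("  words: %s\n", paste(unique(x$word), collapse = ", ")))
  cat(sprintf("  behaviors: %s | blocks: %d\n",
              paste(unique(x$behavior), collapse = ", "),
              length(unique(x$block))))
  invisible(x)
}

#' @export
dim.trial_set <- function(x) dim(x$features)

n_trials <- function(x) dim(x$features)[1L]

#' Window-averaged per-trial feature vectors
#'
#' A `feature_set` is the result of averaging a `trial_set` over a fixed
#' time window: one vector per trial, with labels carried over. These are
#' the vectors all geometry and decoding analyses consume.
#'
#' @param vectors numeric matrix `trials x features`.
#' @param word,behavior,block per-trial labels.
#' @param window length-2 numeric `(start_ms, length_ms)` relative to the
#'   go cue, or `NULL` when the vectors were not produced by windowing.
#' @return An object of class `feature_set`.
#' @export
feature_set <- function(vectors, word, behavior, block, window = NULL) {
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  if (length(word) != n || length(behavior) != n || length(block) != n) {
    stop("labels must match the trial axis of `vectors`")
  }
  if (!all(is.finite(vectors))) stop("feature vectors must be finite")
  structure(
    list(vectors = vectors, word = as.character(word),
         behavior = as.character(behavior), block = as.character(block),
         window = window),
    class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d trials x %d features", nrow(x$vectors),
              ncol(x$vectors)))
  if (!is.null(x$window)) {
    cat(sprintf(" | window %g ms + %g ms", x$window[1], x$window[2]))
  }
  cat("\n")
  invisible(x)
}

#' Subset a feature_set by trial index or by labels
#'
#' @param x a `feature_set`.
#' @param idx integer or logical trial index.
#' @return A `feature_set` containing the selected trials.
#' @export
subset_trials <- function(x, idx) {
  stopifnot(inherits(x, "feature_set"))
  feature_set(x$vectors[idx, , drop = FALSE], x$word[idx], x$behavior[idx],
              x$block[idx], x$window)
}

#' Write / read a session as a portable plain-text bundle
#'
#' Sessions are stored as a directory holding `features.csv` (one row per
#' trial-bin, features as columns) plus `meta.json` with labels, the go
#' bin, bin width, schedule and seed. The format is plain text so sessions
#' can be versioned and inspected with standard tools.
#'
#' @param x a `trial_set`.
#' @param path directory to create (must not be an existing file).
#' @return `write_session` returns `path` invisibly; `read_session`
#'   returns the reconstructed `trial_set`.
#' @export
write_session <- function(x, path) {
  stopifnot(inherits(x, "trial_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(x$features)
  flat <- matrix(aperm(x$features, c(2, 1, 3)), nrow = d[1] * d[2])
  colnames(flat) <- sprintf("f%03d", seq_len(d[3]))
  write.csv(flat, file.path(path, "features.csv"), row.names = FALSE)
  meta <- list(n_trials = d[1], n_bins = d[2], n_features = d[3],
               bin_ms = x$bin_ms, schedule = x$schedule,
               word = x$word, behavior = x$behavior, block = x$block,
               go_bin = x$go_bin)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  flat <- as.matrix(read.csv(file.path(path, "features.csv")))
  features <- aperm(
    array(flat, dim = c(meta$n_bins, meta$n_trials, meta$n_features)),
    c(2, 1, 3))
  trial_set(features, as.numeric(meta$bin_ms), meta$word, meta$behavior,
            meta$block, as.integer(meta$go_bin), meta$schedule)
}
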