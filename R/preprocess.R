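#' Gaussian smoothing, block centering and SD normalization
#'
#' Applies the standard feature conditioning used before all downstream
#' analyses: (1) per-feature temporal smoothing with a Gaussian kernel of
#' SD `sigma_ms` (truncated at 4 SD, renormalized to unit sum so edge bins
#' keep their scale); (2) per-block, per-feature mean subtraction to remove
#' slow firing-rate drift; (3) optionally, division by the per-feature SD
#' computed over all trials and bins of the set, so high-rate features do
#' not dominate population metrics. Features with zero SD are left centered
#' with a warning. Centering precedes normalization.
#'
#' @param trials a [trial_set()].
#' @param sigma_ms Gaussian kernel SD in ms (default 60; 0 disables
#'   smoothing).
#' @param do_std divide by the per-feature SD (default `TRUE`).
#' @return A `trial_set` with conditioned features.
#' @export
smooth_and_normalize <- function(trials, sigma_ms = 60, do_std = TRUE) {
  stopifnot(inherits(trials, "trial_set"))
  if (sigma_ms < 0) stop("sigma_ms must be nonnegative")
  d <- dim(trials$features)
  if (d[1] == 0) stop("empty trial_set")
  x <- trials$features

  if (sigma_ms > 0) {
    S <- smoothing_matrix(d[2], trials$bin_ms, sigma_ms)
    # one multiply over all trials/features: bins-first flattening
    m <- matrix(aperm(x, c(2, 1, 3)), nrow = d[2])
    x <- aperm(array(S %*% m, dim = c(d[2], d[1], d[3])), c(2, 1, 3))
  }

  for (b in unique(trials$block)) {
    idx <- which(trials$block == b)
    if (length(idx) < 2) stop("need at least 2 trials per block to center")
    mu <- colMeans(matrix(x[idx, , ], ncol = d[3]))
    x[idx, , ] <- x[idx, , ] - rep(mu, each = length(idx) * d[2])
  }

  if (do_std) {
    s <- apply(matrix(x, ncol = d[3]), 2, sd)
    zero <- s < .Machine$double.eps^0.5
    if (any(zero)) {
      warning(sprintf("%d zero-SD feature(s) left centered, not scaled",
                      sum(zero)), call. = FALSE)
      s[zero] <- 1
    }
    x <- sweep(x, 3, s, "/")
  }

  out <- trials
  out$features <- x
  out
}

# bins x bins Gaussian smoothing operator, rows renormalized to unit sum
# (truncation at +-4 SD; edge handling by renormalization, no padding)
smoothing_matrix <- function(n_bins, bin_ms, sigma_ms) {
  sigma_bins <- sigma_ms / bin_ms
  half <- ceiling(4 * sigma_bins)
  idx <- seq_len(n_bins)
  S <- outer(idx, idx, function(i, j) {
    w <- exp(-((i - j)^2) / (2 * sigma_bins^2))
    w * (abs(i - j) <= half)
  })
  S / rowSums(S)
}

#' Average features over a decoding window
#'
#' Means each trial's features over the bins whose onsets fall in
#' `[start_ms, start_ms + length_ms)` relative to that trial's go cue, and
#' returns the per-trial vectors with labels carried over.
#'
#' @param trials a [trial_set()] (typically after
#'   [smooth_and_normalize()]).
#' @param start_ms window start relative to the go cue (may be negative
#'   for pre-go windows).
#' @param length_ms window length (default 500).
#' @return A [feature_set()].
#' @export
window_average <- function(trials, start_ms, length_ms = 500) {
  stopifnot(inherits(trials, "trial_set"))
  d <- dim(trials$features)
  vectors <- matrix(NA_real_, d[1], d[3])
  for (i in seq_len(d[1])) {
    onset_ms <- (seq_len(d[2]) - trials$go_bin[i]) * trials$bin_ms
    sel <- onset_ms >= start_ms - 1e-9 &
      onset_ms < start_ms + length_ms - 1e-9
    if (!any(sel)) {
      stop(sprintf("window [%g, %g) ms covers no bins for trial %d",
                   start_ms, start_ms + length_ms, i))
    }
    slab <- trials$features[i, sel, , drop = FALSE]
    vectors[i, ] <- colMeans(matrix(slab, ncol = d[3]))
  }
  feature_set(vectors, trials$word, trials$behavior, trials$block,
              window = c(start_ms, length_ms))
}
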