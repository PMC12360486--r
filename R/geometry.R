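#' Bias-reduced cross-validated Euclidean distance between conditions
#'
#' The naive plug-in distance between two condition means is inflated by
#' observation noise. This estimator averages, over random disjoint
#' half-splits of each condition's trials, the inner product
#' `< mean_a1 - mean_b1, mean_a2 - mean_b2 >`, which is an unbiased
#' estimate of the squared distance between the true means because the two
#' halves carry independent noise. The signed square root is returned
#' (negative estimates are kept rather than clipped, so null distributions
#' stay centered at zero).
#'
#' @param a,b numeric matrices `trials x features` for the two conditions
#'   (at least 2 trials each).
#' @param n_splits number of random half-splits averaged (default 100).
#' @param seed integer seed.
#' @return Scalar `sign(est) * sqrt(|est|)` where `est` estimates the
#'   squared mean distance.
#' @export
cv_distance <- function(a, b, n_splits = 100, seed = 1) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) < 2 || nrow(b) < 2) stop("need at least 2 trials per condition")
  with_seed(seed, {
    est <- mean(vapply(seq_len(n_splits), function(s) {
      ha <- half_split_means(a)
      hb <- half_split_means(b)
      sum((ha[[1]] - hb[[1]]) * (ha[[2]] - hb[[2]]))
    }, numeric(1)))
    sign(est) * sqrt(abs(est))
  })
}

half_split_means <- function(x) {
  n <- nrow(x)
  perm <- sample.int(n)
  h <- floor(n / 2)
  list(colMeans(x[perm[seq_len(h)], , drop = FALSE]),
       colMeans(x[perm[(h + 1):n], , drop = FALSE]))
}

#' Bias-reduced cross-validated correlation between condition patterns
#'
#' The sample correlation between two noisy condition means is biased
#' toward zero because noise inflates the magnitude terms in its
#' denominator. Here each magnitude is estimated as the cross-split inner
#' product of the condition with itself (unbiased for the squared norm of
#' the true pattern), and the numerator as the cross-split inner product
#' between conditions. The resulting estimate may legitimately exceed 1
#' in magnitude when modulation is weak; values beyond 1 should be read as
#' evidence that the true correlation is near 1. When an estimated
#' squared magnitude is nonpositive the correlation is undefined and
#' `NaN` is returned with a warning.
#'
#' Patterns are expected to already be mean-subtracted (see
#' [subtract_word_mean()]) when used on per-word vectors.
#'
#' @inheritParams cv_distance
#' @return Scalar correlation estimate (possibly outside `[-1, 1]`).
#' @export
cv_correlation <- function(a, b, n_splits = 100, seed = 1) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) < 2 || nrow(b) < 2) stop("need at least 2 trials per condition")
  with_seed(seed, {
    acc <- vapply(seq_len(n_splits), function(s) {
      ha <- half_split_means(a)
      hb <- half_split_means(b)
      c(num = 0.5 * (sum(ha[[1]] * hb[[2]]) + sum(ha[[2]] * hb[[1]])),
        da = sum(ha[[1]] * ha[[2]]),
        db = sum(hb[[1]] * hb[[2]]))
    }, numeric(3))
    m <- rowMeans(acc)
    if (m[["da"]] <= 0 || m[["db"]] <= 0) {
      warning("nonpositive cross-validated magnitude; correlation undefined",
              call. = FALSE)
      return(NaN)
    }
    m[["num"]] / (sqrt(m[["da"]]) * sqrt(m[["db"]]))
  })
}

#' Subtract the per-behavior grand mean across words
#'
#' Before correlating word patterns, the mean feature vector across all
#' words (all trials) within each behavior is removed, so that
#' correlations reflect word-specific modulation rather than shared
#' behavior offsets.
#'
#' @param fvs a [feature_set()].
#' @return A `feature_set` of mean-subtracted vectors.
#' @export
subtract_word_mean <- function(fvs) {
  stopifnot(inherits(fvs, "feature_set"))
  v <- fvs$vectors
  for (b in unique(fvs$behavior)) {
    idx <- fvs$behavior == b
    v[idx, ] <- sweep(v[idx, , drop = FALSE], 2,
                      colMeans(v[idx, , drop = FALSE]))
  }
  out <- fvs
  out$vectors <- v
  out
}

#' Per-trial behavior vectors (word patterns concatenated)
#'
#' For whole-behavior correlations, one "behavior vector" per trial index
#' is built by concatenating that index's mean-subtracted vectors for
#' every word (words truncated to the smallest per-word trial count). Call
#' [subtract_word_mean()] first.
#'
#' @param fvs a mean-subtracted [feature_set()].
#' @param behavior behavior label to extract.
#' @return Matrix `min_trials x (n_words * n_features)`.
#' @export
behavior_vectors <- function(fvs, behavior) {
  stopifnot(inherits(fvs, "feature_set"))
  idx <- fvs$behavior == behavior
  if (!any(idx)) stop(sprintf("behavior '%s' not present", behavior))
  words <- sort(unique(fvs$word[idx]))
  per_word <- lapply(words, function(w)
    fvs$vectors[idx & fvs$word == w, , drop = FALSE])
  n <- min(vapply(per_word, nrow, integer(1)))
  do.call(cbind, lapply(per_word, function(m) m[seq_len(n), , drop = FALSE]))
}

#' Mean within-behavior word-pair distances, normalized to a reference
#'
#' For each behavior, averages the cross-validated distance over all word
#' pairs, then divides by the reference behavior's average so the
#' reference row is 1 by construction. The ratio for a behavior recovers
#' its modulation scale relative to the reference.
#'
#' @param fvs a [feature_set()] containing all behaviors of interest.
#' @param reference_behavior behavior used as the denominator (default
#'   `"attempted"`).
#' @param n_splits,seed passed to [cv_distance()].
#' @return Data frame with columns `behavior`, `mean_distance`,
#'   `normalized`, `n_pairs`.
#' @export
normalized_distances <- function(fvs, reference_behavior = "attempted",
                                 n_splits = 100, seed = 1) {
  stopifnot(inherits(fvs, "feature_set"))
  behaviors <- unique(fvs$behavior)
  if (!reference_behavior %in% behaviors) {
    stop(sprintf("reference behavior '%s' not present", reference_behavior))
  }
  rows <- lapply(behaviors, function(b) {
    idx <- fvs$behavior == b
    words <- sort(unique(fvs$word[idx]))
    if (length(words) < 2) stop(sprintf("behavior '%s' has < 2 words", b))
    pairs <- utils::combn(words, 2)
    d <- vapply(seq_len(ncol(pairs)), function(p) {
      cv_distance(fvs$vectors[idx & fvs$word == pairs[1, p], , drop = FALSE],
                  fvs$vectors[idx & fvs$word == pairs[2, p], , drop = FALSE],
                  n_splits = n_splits, seed = seed + p)
    }, numeric(1))
    data.frame(behavior = b, mean_distance = mean(d), n_pairs = ncol(pairs))
  })
  out <- do.call(rbind, rows)
  ref <- out$mean_distance[out$behavior == reference_behavior]
  out$normalized <- out$mean_distance / ref
  out[, c("behavior", "mean_distance", "normalized", "n_pairs")]
}

#' Condition-mean matrix from a feature set
#'
#' @param fvs a [feature_set()].
#' @return Matrix `conditions x features` with rownames
#'   `"behavior:word"`, plus attributes `behavior` and `word`.
#' @export
condition_means <- function(fvs) {
  stopifnot(inherits(fvs, "feature_set"))
  conds <- unique(data.frame(behavior = fvs$behavior, word = fvs$word))
  conds <- conds[order(conds$behavior, conds$word), ]
  m <- t(vapply(seq_len(nrow(conds)), function(i) {
    idx <- fvs$behavior == conds$behavior[i] & fvs$word == conds$word[i]
    colMeans(fvs$vectors[idx, , drop = FALSE])
  }, numeric(ncol(fvs$vectors))))
  rownames(m) <- paste(conds$behavior, conds$word, sep = ":")
  attr(m, "behavior") <- conds$behavior
  attr(m, "word") <- conds$word
  m
}

#' Project condition means onto top principal components ("word rings")
#'
#' Fits PCA on a chosen subset of condition means (for example only the
#' attempted-speech words, or all conditions of an interleaved task) and
#' projects every condition into the top components. Connecting a
#' behavior's projected words in order draws its "word ring"; congruent
#' rings at different scales indicate a shared word code, and displacement
#' between rings reveals a behavior-offset dimension.
#'
#' @param mean_vectors matrix `conditions x features` (see
#'   [condition_means()]).
#' @param fit_idx indices (or logical) of the conditions used to fit the
#'   components; defaults to all conditions.
#' @param n_components number of components (default 3; reduced with a
#'   warning when rank is lower).
#' @return List with `projections` (conditions x components),
#'   `explained` (variance fractions), and the `prcomp` fit.
#' @export
pca_word_rings <- function(mean_vectors, fit_idx = NULL, n_components = 3) {
  m <- as.matrix(mean_vectors)
  if (is.null(fit_idx)) fit_idx <- seq_len(nrow(m))
  fit <- m[fit_idx, , drop = FALSE]
  if (nrow(fit) < 2) stop("need at least 2 conditions to fit components")
  max_rank <- qr(scale(fit, scale = FALSE))$rank
  if (max_rank < n_components) {
    warning(sprintf("rank %d < %d requested components; reducing",
                    max_rank, n_components), call. = FALSE)
    n_components <- max_rank
  }
  pc <- prcomp(fit, center = TRUE, scale. = FALSE)
  proj <- sweep(m, 2, pc$center) %*% pc$rotation[, seq_len(n_components),
                                                 drop = FALSE]
  rownames(proj) <- rownames(m)
  explained <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)]
  list(projections = proj, explained = explained, fit = pc)
}
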