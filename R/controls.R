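#' Articulatory-length control regression
#'
#' Tests whether pairwise differences in word duration predict pairwise
#' neural distances. If decoding were driven merely by word length,
#' longer duration differences would evoke larger neural distances; an
#' OLS fit (with intercept) of neural distance on `|duration_i -
#' duration_j|` with a two-tailed t-test on the slope quantifies this.
#'
#' @param word_durations_ms named numeric vector, one duration per word.
#' @param distances data frame with columns `word_i`, `word_j`,
#'   `distance` covering all word pairs (at least 3).
#' @return An object of class `slope_result`: `slope`, `intercept`,
#'   `p_two_tailed`, `n_points`.
#' @export
ols_length_control <- function(word_durations_ms, distances) {
  need <- c("word_i", "word_j", "distance")
  if (!all(need %in% names(distances))) {
    stop("distances needs columns word_i, word_j, distance")
  }
  if (nrow(distances) < 3) stop("need at least 3 word pairs")
  miss <- setdiff(c(distances$word_i, distances$word_j),
                  names(word_durations_ms))
  if (length(miss)) {
    stop("durations missing for: ", paste(unique(miss), collapse = ", "))
  }
  dd <- abs(word_durations_ms[distances$word_i] -
              word_durations_ms[distances$word_j])
  if (var(dd) == 0) stop("zero variance in duration differences")
  fit <- lm(distances$distance ~ dd)
  slope_result(fit, nrow(distances))
}

slope_result <- function(fit, n_points, null_slopes = NULL) {
  # exact fits (noiseless worked examples) trip lm's perfect-fit warning
  cf <- suppressWarnings(summary(fit))$coefficients
  structure(
    list(slope = unname(cf[2, 1]), intercept = unname(cf[1, 1]),
         p_two_tailed = unname(cf[2, 4]), n_points = n_points,
         null_slopes = null_slopes),
    class = "slope_result")
}

#' @export
print.slope_result <- function(x, ...) {
  cat(sprintf("<slope_result> slope %.4g (p = %.3g, n = %d)\n",
              x$slope, x$p_two_tailed, x$n_points))
  invisible(x)
}

#' Counting-slope regression
#'
#' Pools `(position, decoded number)` points across all counting trials
#' (positions indexed from 0; the slope is origin-invariant) and fits an
#' OLS line. A significantly positive slope indicates that decoded
#' numbers increase over the course of the trials, as expected if the
#' participant counts with inner speech.
#'
#' @param decoded_sequences list of numeric vectors (decoded number words
#'   per trial).
#' @return A `slope_result`.
#' @export
counting_slope <- function(decoded_sequences) {
  decoded_sequences <- decoded_sequences[lengths(decoded_sequences) > 0]
  if (!length(decoded_sequences)) stop("all sequences empty")
  pos <- unlist(lapply(decoded_sequences, function(s) seq_along(s) - 1))
  val <- unlist(decoded_sequences)
  if (var(pos) == 0) stop("need at least one sequence of length > 1")
  slope_result(lm(val ~ pos), length(val))
}

# closed-form OLS slope for resampling loops
fast_slope <- function(pos, val) {
  pm <- mean(pos)
  sum((pos - pm) * val) / sum((pos - pm)^2)
}

#' Stitched-trial null distribution for the counting slope
#'
#' Builds a null for the counting slope from control sequences that carry
#' no counting structure (for example numbers decoded from free sentence
#' trials): each pseudo-trial concatenates `stitch_k` randomly chosen
#' control sequences so its length matches a counting trial, `n_trials`
#' pseudo-trials form one resample, and the pooled slope is recorded over
#' `n_resamples` resamples.
#'
#' @param control_sequences list of numeric vectors without positional
#'   structure.
#' @param n_trials pseudo-trials per resample (match the real counting
#'   trial count).
#' @param stitch_k control sequences concatenated per pseudo-trial
#'   (default 3).
#' @param n_resamples resamples (default 1000).
#' @param seed integer seed.
#' @param observed_slope optional observed counting slope to locate in
#'   the null.
#' @return List with `null_slopes` and, when `observed_slope` is given,
#'   `percentile` (percent of null at or below the observed slope).
#' @export
stitched_null <- function(control_sequences, n_trials, stitch_k = 3,
                          n_resamples = 1000, seed = 1,
                          observed_slope = NULL) {
  control_sequences <- control_sequences[lengths(control_sequences) > 0]
  if (length(control_sequences) < stitch_k) {
    stop("need at least stitch_k control sequences")
  }
  with_seed(seed, {
    null_slopes <- vapply(seq_len(n_resamples), function(r) {
      pos <- integer(0); val <- numeric(0)
      for (t in seq_len(n_trials)) {
        pick <- sample.int(length(control_sequences), stitch_k,
                           replace = TRUE)
        stitched <- unlist(control_sequences[pick])
        pos <- c(pos, seq_along(stitched) - 1L)
        val <- c(val, stitched)
      }
      fast_slope(pos, val)
    }, numeric(1))
    out <- list(null_slopes = null_slopes)
    if (!is.null(observed_slope)) {
      out$percentile <- 100 * mean(null_slopes <= observed_slope)
    }
    out
  })
}

#' Bootstrap mean word counts per prompt category
#'
#' Bootstraps the mean number of decoded words per trial for each prompt
#' category (for example verbal thought, autobiographical thought, clear
#' your mind) and flags category pairs whose 95% intervals do not
#' overlap.
#'
#' @param word_counts_by_category named list of numeric vectors.
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed integer seed.
#' @param alpha interval level (default 0.05).
#' @return List with `summary` (data frame: category, mean, ci_low,
#'   ci_high, n) and `non_overlap` (data frame of category pairs with a
#'   logical `distinct`).
#' @export
prompt_wordcount_contrast <- function(word_counts_by_category,
                                      n_boot = 10000, seed = 1,
                                      alpha = 0.05) {
  cats <- names(word_counts_by_category)
  if (is.null(cats) || any(!nzchar(cats))) stop("categories must be named")
  if (any(lengths(word_counts_by_category) == 0)) {
    stop("every category needs at least one count")
  }
  with_seed(seed, {
    summ <- do.call(rbind, lapply(cats, function(cat) {
      x <- word_counts_by_category[[cat]]
      boots <- vapply(seq_len(n_boot), function(b)
        mean(x[sample.int(length(x), replace = TRUE)]), numeric(1))
      ci <- unname(quantile(boots, c(alpha / 2, 1 - alpha / 2), type = 7))
      data.frame(category = cat, mean = mean(x),
                 ci_low = ci[1], ci_high = ci[2], n = length(x))
    }))
    non_overlap <- NULL
    if (length(cats) >= 2) {
      pairs <- utils::combn(cats, 2)
      non_overlap <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(p) {
        a <- summ[summ$category == pairs[1, p], ]
        b <- summ[summ$category == pairs[2, p], ]
        data.frame(category_a = pairs[1, p], category_b = pairs[2, p],
                   distinct = a$ci_high < b$ci_low || b$ci_high < a$ci_low)
      }))
    }
    list(summary = summ, non_overlap = non_overlap)
  })
}

#' Word-pair distance table for a behavior
#'
#' Convenience wrapper producing the pairwise cross-validated distance
#' table that [ols_length_control()] consumes.
#'
#' @param fvs a [feature_set()].
#' @param behavior behavior to analyse.
#' @param n_splits,seed passed to [cv_distance()].
#' @return Data frame with `word_i`, `word_j`, `distance`.
#' @export
word_pair_distances <- function(fvs, behavior, n_splits = 100, seed = 1) {
  stopifnot(inherits(fvs, "feature_set"))
  idx <- fvs$behavior == behavior
  words <- sort(unique(fvs$word[idx]))
  pairs <- utils::combn(words, 2)
  d <- vapply(seq_len(ncol(pairs)), function(p) {
    cv_distance(fvs$vectors[idx & fvs$word == pairs[1, p], , drop = FALSE],
                fvs$vectors[idx & fvs$word == pairs[2, p], , drop = FALSE],
                n_splits = n_splits, seed = seed + p)
  }, numeric(1))
  data.frame(word_i = pairs[1, ], word_j = pairs[2, ], distance = d)
}
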