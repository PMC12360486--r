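#' Exact Clopper-Pearson binomial confidence interval
#'
#' Exact two-sided interval for a binomial proportion via Beta quantiles:
#' `low = qbeta(alpha/2, s, n - s + 1)`, `high = qbeta(1 - alpha/2, s + 1,
#' n - s)`, with `low = 0` at `s = 0` and `high = 1` at `s = n`.
#'
#' @param successes,n counts with `0 <= successes <= n`, `n >= 1`.
#' @param alpha two-sided level (default 0.05).
#' @return List with `low`, `high`, `alpha`.
#' @export
clopper_pearson <- function(successes, n, alpha = 0.05) {
  if (n < 1) stop("n must be at least 1")
  if (successes < 0 || successes > n) stop("successes must lie in [0, n]")
  low <- if (successes == 0) 0 else qbeta(alpha / 2, successes,
                                          n - successes + 1)
  high <- if (successes == n) 1 else qbeta(1 - alpha / 2, successes + 1,
                                           n - successes)
  list(low = low, high = high, alpha = alpha)
}

# Gaussian naive Bayes on a trials x features matrix. Per-class feature
# means and (MLE) variances with a small floor; equal-prior-free log
# posterior via matrix products.
gnb_fit <- function(x, y, var_floor = 1e-9) {
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need at least 2 classes")
  mu <- t(vapply(classes, function(cl) colMeans(x[y == cl, , drop = FALSE]),
                 numeric(ncol(x))))
  v <- t(vapply(classes, function(cl) {
    xi <- x[y == cl, , drop = FALSE]
    colMeans(xi^2) - colMeans(xi)^2
  }, numeric(ncol(x))))
  v <- pmax(v, var_floor)
  prior <- as.numeric(table(factor(y, levels = classes))) / length(y)
  list(classes = classes, mu = mu, var = v, log_prior = log(prior))
}

gnb_predict <- function(model, x) {
  # log N(x; mu, v) summed over features, for all classes at once:
  # -0.5 * [ sum log(2 pi v) + x^2 (1/v)' - 2 x (mu/v)' + sum(mu^2/v) ]
  inv_v <- 1 / model$var
  const <- -0.5 * rowSums(log(2 * pi * model$var)) -
    0.5 * rowSums(model$mu^2 * inv_v)
  ll <- -0.5 * (x^2) %*% t(inv_v) + x %*% t(model$mu * inv_v)
  ll <- sweep(ll, 2, const + model$log_prior, "+")
  model$classes[max.col(ll, ties.method = "first")]
}

#' Nested cross-validated Gaussian naive Bayes word decoding
#'
#' Decodes the word label from window-averaged features with a nested
#' k-fold design that optimizes the decoding-window start time without
#' leaking test data: within each outer training fold, an inner k-fold
#' accuracy is computed for every candidate window start, the best start
#' (ties broken toward the earliest) is selected, and a classifier trained
#' with that window on the full outer training set is applied to the outer
#' test fold. Test-fold success indicators are concatenated across outer
#' folds; the reported accuracy carries an exact Clopper-Pearson interval,
#' and decoding is flagged significant when the interval's lower bound
#' exceeds chance (1 / number of classes).
#'
#' @param trials a smoothed/normalized [trial_set()].
#' @param candidate_starts numeric vector of window start times (ms
#'   relative to the go cue).
#' @param window_ms decoding-window length (default 500).
#' @param k_outer,k_inner fold counts (default 10 each).
#' @param seed integer seed controlling fold assignment.
#' @param alpha level for the Clopper-Pearson interval.
#' @param label decode `"word"` (default) or the `"word:behavior"`
#'   combination (`"condition"`).
#' @return An object of class `decode_result`: `predictions`, `truth`,
#'   `accuracy`, `ci`, `confusion`, `chosen_window_per_fold`, `chance`,
#'   `significant`.
#' @export
nested_cv_gnb <- function(trials, candidate_starts, window_ms = 500,
                          k_outer = 10, k_inner = 10, seed = 1,
                          alpha = 0.05, label = c("word", "condition")) {
  stopifnot(inherits(trials, "trial_set"))
  label <- match.arg(label)
  if (!length(candidate_starts)) stop("candidate_starts must be nonempty")
  candidate_starts <- sort(candidate_starts)

  y <- if (label == "word") trials$word
       else paste(trials$word, trials$behavior, sep = ":")
  fsets <- lapply(candidate_starts, function(s)
    window_average(trials, s, window_ms)$vectors)

  with_seed(seed, {
    outer_folds <- stratified_folds(y, k_outer)
    n <- length(y)
    predictions <- character(n)
    chosen <- numeric(k_outer)
    for (f in seq_len(k_outer)) {
      test <- which(outer_folds == f)
      train <- which(outer_folds != f)
      best <- 1L
      if (length(candidate_starts) > 1L) {
        inner_folds <- stratified_folds(y[train], k_inner)
        acc <- vapply(seq_along(candidate_starts), function(ci) {
          x <- fsets[[ci]][train, , drop = FALSE]
          correct <- 0L
          for (g in seq_len(k_inner)) {
            tr <- inner_folds != g
            m <- gnb_fit(x[tr, , drop = FALSE], y[train][tr])
            correct <- correct +
              sum(gnb_predict(m, x[!tr, , drop = FALSE]) == y[train][!tr])
          }
          correct / length(train)
        }, numeric(1))
        best <- which.max(acc)  # ties resolve to the earliest start
      }
      chosen[f] <- candidate_starts[best]
      m <- gnb_fit(fsets[[best]][train, , drop = FALSE], y[train])
      predictions[test] <- gnb_predict(m, fsets[[best]][test, , drop = FALSE])
    }

    successes <- sum(predictions == y)
    ci <- clopper_pearson(successes, n, alpha)
    classes <- sort(unique(y))
    chance <- 1 / length(classes)
    structure(
      list(predictions = predictions, truth = y,
           accuracy = successes / n, ci = ci,
           confusion = table(true = factor(y, classes),
                             predicted = factor(predictions, classes)),
           chosen_window_per_fold = chosen,
           chance = chance, significant = ci$low > chance),
      class = "decode_result")
  })
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf(
    "<decode_result> accuracy %.1f%% (95%% CI [%.1f%%, %.1f%%]), chance %.1f%%%s\n",
    100 * x$accuracy, 100 * x$ci$low, 100 * x$ci$high, 100 * x$chance,
    if (x$significant) ", significant" else ""))
  if (length(unique(x$chosen_window_per_fold)) > 1 ||
      !is.na(x$chosen_window_per_fold[1])) {
    cat("  chosen window starts (ms): ",
        paste(x$chosen_window_per_fold, collapse = " "), "\n", sep = "")
  }
  invisible(x)
}
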