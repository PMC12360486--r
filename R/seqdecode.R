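#' Sequence-memory trial container
#'
#' Window-summed preparatory activity for an instructed-delay sequence
#' task: one feature vector per trial plus the cued symbol sequence, the
#' instructed mental strategy and a task label.
#'
#' @param features numeric matrix `trials x features`, nonnegative.
#' @param sequences character matrix `trials x positions` of direction
#'   symbols.
#' @param strategy `"none"`, `"verbal"` or `"visual"`.
#' @param task free-form task label.
#' @return An object of class `sequence_trial_set`.
#' @export
sequence_trial_set <- function(features, sequences,
                               strategy = c("none", "verbal", "visual"),
                               task = "arrows") {
  strategy <- match.arg(strategy)
  features <- as.matrix(features)
  sequences <- as.matrix(sequences)
  if (nrow(features) != nrow(sequences)) {
    stop("features and sequences must have one row per trial")
  }
  if (any(features < 0)) stop("window-summed features must be nonnegative")
  structure(
    list(features = features, sequences = sequences,
         strategy = strategy, task = task),
    class = "sequence_trial_set")
}

#' @export
print.sequence_trial_set <- function(x, ...) {
  cat(sprintf(
    "<sequence_trial_set> %d trials x %d features | %d-position sequences, %d conditions (%s, %s)\n",
    nrow(x$features), ncol(x$features), ncol(x$sequences),
    length(unique(apply(x$sequences, 1, paste, collapse = ""))),
    x$strategy, x$task))
  invisible(x)
}

cov_safe <- function(x) {
  if (nrow(x) < 2) return(matrix(0, ncol(x), ncol(x)))
  stats::cov(x)
}

# Binary LDA with the pooled covariance shrunk toward its diagonal for
# small-sample stability: Sigma = (1 - g) S + g diag(S).
lda_binary_fit <- function(x, y, shrinkage = 0.1) {
  classes <- sort(unique(y))
  if (length(classes) != 2) stop("binary LDA needs exactly 2 classes")
  x0 <- x[y == classes[1], , drop = FALSE]
  x1 <- x[y == classes[2], , drop = FALSE]
  mu0 <- colMeans(x0); mu1 <- colMeans(x1)
  pool <- ((nrow(x0) - 1) * cov_safe(x0) + (nrow(x1) - 1) * cov_safe(x1)) /
    (nrow(x0) + nrow(x1) - 2)
  sig <- (1 - shrinkage) * pool + shrinkage * diag(diag(pool),
                                                   ncol(x), ncol(x))
  # guard against singularity when shrinkage = 0 on degenerate data
  w <- tryCatch(solve(sig, mu1 - mu0),
                error = function(e) MASS_free_solve(sig, mu1 - mu0))
  b <- sum(w * (mu0 + mu1)) / 2 -
    log(nrow(x1) / nrow(x0))
  list(classes = classes, w = w, b = b)
}

# ridge fallback for an exactly singular pooled covariance
MASS_free_solve <- function(sig, d) {
  solve(sig + diag(1e-8 * mean(diag(sig)) + 1e-12, nrow(sig)), d)
}

lda_binary_predict <- function(model, x) {
  score <- drop(x %*% model$w) - model$b
  model$classes[ifelse(score > 0, 2L, 1L)]
}

seq_keys <- function(tset) apply(tset$sequences, 1, paste, collapse = "|")

# all unordered pairs of sequence conditions differing only at `position`
qualifying_pairs <- function(sequences, position) {
  useq <- unique(sequences)
  keys <- apply(useq, 1, paste, collapse = "|")
  pairs <- list()
  if (nrow(useq) >= 2) {
    for (i in seq_len(nrow(useq) - 1)) {
      for (j in (i + 1):nrow(useq)) {
        differs <- useq[i, ] != useq[j, ]
        if (sum(differs) == 1 && which(differs) == position) {
          pairs[[length(pairs) + 1L]] <- c(keys[i], keys[j])
        }
      }
    }
  }
  pairs
}

#' Position-wise binary LDA decoding of sequence identity
#'
#' For every pair of sequence conditions that differ at exactly one
#' position (the queried one), a binary LDA decoder is cross-validated and
#' its per-trial outcomes retained. Holding the remaining positions
#' constant within each pair avoids sequence-context confounds. The
#' pooled per-position accuracy weights pairs by their trial counts.
#'
#' @param tset a [sequence_trial_set()].
#' @param position sequence position to decode (1-based).
#' @param k_folds cross-validation folds (default 5).
#' @param seed integer seed.
#' @param shrinkage LDA covariance shrinkage toward the diagonal
#'   (default 0.1).
#' @return An object of class `position_decode_result`: `position`,
#'   `pairs` (per-pair key, accuracy and outcome vector) and
#'   `pooled_accuracy`.
#' @export
positionwise_pair_decode <- function(tset, position, k_folds = 5, seed = 1,
                                     shrinkage = 0.1) {
  stopifnot(inherits(tset, "sequence_trial_set"))
  pairs <- qualifying_pairs(tset$sequences, position)
  if (!length(pairs)) stop(sprintf("no qualifying pairs at position %d",
                                   position))
  keys <- seq_keys(tset)
  with_seed(seed, {
    out <- lapply(pairs, function(p) {
      idx <- which(keys %in% p)
      y <- keys[idx]
      folds <- stratified_folds(y, k_folds)
      correct <- logical(length(idx))
      for (f in seq_len(k_folds)) {
        tr <- folds != f
        m <- lda_binary_fit(tset$features[idx[tr], , drop = FALSE], y[tr],
                            shrinkage)
        correct[!tr] <-
          lda_binary_predict(m, tset$features[idx[!tr], , drop = FALSE]) ==
          y[!tr]
      }
      list(pair = p, outcomes = correct, accuracy = mean(correct))
    })
    structure(
      list(position = position, pairs = out,
           pooled_accuracy =
             mean(unlist(lapply(out, `[[`, "outcomes")))),
      class = "position_decode_result")
  })
}

#' @export
print.position_decode_result <- function(x, ...) {
  cat(sprintf(
    "<position_decode_result> position %d: %d pair decoder(s), pooled accuracy %.3f\n",
    x$position, length(x$pairs), x$pooled_accuracy))
  invisible(x)
}

#' Bootstrap confidence interval for per-position decoding accuracy
#'
#' Resamples every pair decoder's cross-validated outcomes with
#' replacement, pools within the position, and repeats `n_boot` times.
#' The interval is the 2.5th-97.5th percentile range; decoding is called
#' significant when the 2.5th percentile exceeds chance (0.5).
#'
#' @param result a `position_decode_result`.
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed integer seed.
#' @return List with `ci` (low, high), `significant`, `boot_acc`.
#' @export
bootstrap_ci_positions <- function(result, n_boot = 10000, seed = 1) {
  stopifnot(inherits(result, "position_decode_result"))
  outcomes <- lapply(result$pairs, `[[`, "outcomes")
  if (!length(outcomes) || !sum(lengths(outcomes))) stop("empty outcomes")
  n_tot <- sum(lengths(outcomes))
  with_seed(seed, {
    boot_acc <- vapply(seq_len(n_boot), function(i) {
      s <- vapply(outcomes, function(o)
        sum(o[sample.int(length(o), replace = TRUE)]), numeric(1))
      sum(s) / n_tot
    }, numeric(1))
    ci <- unname(quantile(boot_acc, c(0.025, 0.975), type = 7))
    list(ci = ci, significant = ci[1] > 0.5, boot_acc = boot_acc)
  })
}

#' Paired verbal-versus-visual accuracy difference
#'
#' Bootstraps the difference in pooled accuracy between two position
#' decode results whose pair decoders match one-to-one (same sequence
#' pair, same position), as when the only change is the instructed mental
#' strategy. Significant when the 2.5th percentile of the difference
#' (`a - b`) exceeds zero.
#'
#' @param result_a,result_b matched `position_decode_result` objects
#'   (for example verbal and visual strategy).
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed integer seed.
#' @return List with `delta` (observed difference), `ci`, `significant`,
#'   `boot_delta`.
#' @export
paired_strategy_delta <- function(result_a, result_b, n_boot = 10000,
                                  seed = 1) {
  stopifnot(inherits(result_a, "position_decode_result"),
            inherits(result_b, "position_decode_result"))
  key <- function(p) paste(sort(p$pair), collapse = "~")
  ka <- vapply(result_a$pairs, key, character(1))
  kb <- vapply(result_b$pairs, key, character(1))
  if (!setequal(ka, kb) || anyDuplicated(ka)) {
    stop("decoder sets are not pairable across results")
  }
  ob <- lapply(result_b$pairs, `[[`, "outcomes")[match(ka, kb)]
  oa <- lapply(result_a$pairs, `[[`, "outcomes")
  na <- sum(lengths(oa)); nb <- sum(lengths(ob))
  with_seed(seed, {
    boot_delta <- vapply(seq_len(n_boot), function(i) {
      sa <- sum(vapply(oa, function(o)
        sum(o[sample.int(length(o), replace = TRUE)]), numeric(1))) / na
      sb <- sum(vapply(ob, function(o)
        sum(o[sample.int(length(o), replace = TRUE)]), numeric(1))) / nb
      sa - sb
    }, numeric(1))
    ci <- unname(quantile(boot_delta, c(0.025, 0.975), type = 7))
    list(delta = result_a$pooled_accuracy - result_b$pooled_accuracy,
         ci = ci, significant = ci[1] > 0, boot_delta = boot_delta)
  })
}

#' Cross-task position decoding
#'
#' Fits one LDA per qualifying pair on all training-task trials and
#' evaluates it on the matching pair of the test task (no folding across
#' tasks). Above-chance transfer indicates a representation shared
#' between tasks at that position.
#'
#' @param train,test [sequence_trial_set()]s sharing the direction
#'   vocabulary at `position`.
#' @param position sequence position (1-based).
#' @param shrinkage LDA shrinkage (default 0.1).
#' @return A `position_decode_result` over the test-task trials.
#' @export
cross_task_decode <- function(train, test, position, shrinkage = 0.1) {
  stopifnot(inherits(train, "sequence_trial_set"),
            inherits(test, "sequence_trial_set"))
  pairs_train <- qualifying_pairs(train$sequences, position)
  pairs_test <- qualifying_pairs(test$sequences, position)
  key <- function(p) paste(sort(p), collapse = "~")
  shared <- intersect(vapply(pairs_train, key, character(1)),
                      vapply(pairs_test, key, character(1)))
  if (!length(shared)) stop("no shared sequence pairs between tasks")
  keys_train <- seq_keys(train)
  keys_test <- seq_keys(test)
  out <- lapply(pairs_train[vapply(pairs_train, key, character(1)) %in%
                              shared], function(p) {
    tr <- which(keys_train %in% p)
    te <- which(keys_test %in% p)
    m <- lda_binary_fit(train$features[tr, , drop = FALSE], keys_train[tr],
                        shrinkage)
    correct <- lda_binary_predict(m, test$features[te, , drop = FALSE]) ==
      keys_test[te]
    list(pair = p, outcomes = correct, accuracy = mean(correct))
  })
  structure(
    list(position = position, pairs = out,
         pooled_accuracy = mean(unlist(lapply(out, `[[`, "outcomes")))),
    class = "position_decode_result")
}
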