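#' Fit the motor-intent dimension from two behaviors
#'
#' The motor-intent dimension is the unit vector pointing from the
#' inner-speech grand centroid to the attempted-speech grand centroid in
#' neural feature space. Centroids are computed by averaging each word's
#' trial mean and then averaging across words, so unequal trial counts per
#' word do not bias the estimate toward frequent words. The data should
#' come from an interleaved-schedule session: when behaviors are mixed
#' within blocks, block-wise mean subtraction leaves the behavior contrast
#' intact while removing drift.
#'
#' @param fvs a [feature_set()] containing both behaviors.
#' @param attempted,inner the two behavior labels (defaults `"attempted"`
#'   and `"inner"`).
#' @return An object of class `motor_intent_model` with fields
#'   `centroid_attempted`, `centroid_inner`, `direction` (unit norm) and
#'   `magnitude`.
#' @export
fit_motor_intent <- function(fvs, attempted = "attempted", inner = "inner") {
  stopifnot(inherits(fvs, "feature_set"))
  for (b in c(attempted, inner)) {
    if (!b %in% fvs$behavior) stop(sprintf("behavior '%s' not present", b))
  }
  centroid <- function(b) {
    idx <- fvs$behavior == b
    words <- unique(fvs$word[idx])
    word_means <- vapply(words, function(w)
      colMeans(fvs$vectors[idx & fvs$word == w, , drop = FALSE]),
      numeric(ncol(fvs$vectors)))
    rowMeans(word_means)
  }
  c_as <- centroid(attempted)
  c_is <- centroid(inner)
  diff <- c_as - c_is
  mag <- sqrt(sum(diff^2))
  if (mag < 1e-9) stop("no separable motor-intent direction")
  structure(
    list(centroid_attempted = c_as, centroid_inner = c_is,
         direction = diff / mag, magnitude = mag,
         behaviors = c(attempted = attempted, inner = inner)),
    class = "motor_intent_model")
}

#' @export
print.motor_intent_model <- function(x, ...) {
  cat(sprintf("<motor_intent_model> %d features, magnitude %.4g\n",
              length(x$direction), x$magnitude))
  invisible(x)
}

#' Project the motor-intent dimension out of feature vectors
#'
#' Each vector `x` is replaced by its residual `x - (x . v) v`, which is
#' orthogonal to the motor-intent direction `v`. The operation is
#' idempotent and leaves vectors already orthogonal to `v` unchanged.
#'
#' @param x a [feature_set()] or a numeric matrix `trials x features`.
#' @param model a `motor_intent_model` from [fit_motor_intent()].
#' @return Object of the same kind as `x` with the projection removed.
#' @export
remove_motor_intent <- function(x, model) {
  stopifnot(inherits(model, "motor_intent_model"))
  v <- model$direction
  project_out <- function(m) {
    if (ncol(m) != length(v)) stop("dimension mismatch")
    m - (m %*% v) %*% t(v)
  }
  if (inherits(x, "feature_set")) {
    x$vectors <- project_out(x$vectors)
    x
  } else {
    project_out(as.matrix(x))
  }
}

#' Decompose 14-class predictions into word and behavior accuracy
#'
#' For a classifier over all word-behavior combinations, word accuracy is
#' the fraction of trials whose predicted word matches irrespective of the
#' predicted behavior, and behavior accuracy the converse. Each carries an
#' exact Clopper-Pearson interval.
#'
#' @param true_word,true_behavior,pred_word,pred_behavior aligned label
#'   vectors.
#' @param alpha interval level (default 0.05).
#' @return List with `word_accuracy`, `behavior_accuracy`, `word_ci`,
#'   `behavior_ci`, `n`.
#' @export
word_behavior_accuracy <- function(true_word, true_behavior,
                                   pred_word, pred_behavior, alpha = 0.05) {
  n <- length(true_word)
  if (n == 0) stop("empty input")
  if (length(true_behavior) != n || length(pred_word) != n ||
      length(pred_behavior) != n) {
    stop("label vectors must be aligned")
  }
  ws <- sum(pred_word == true_word)
  bs <- sum(pred_behavior == true_behavior)
  list(word_accuracy = ws / n, behavior_accuracy = bs / n,
       word_ci = clopper_pearson(ws, n, alpha),
       behavior_ci = clopper_pearson(bs, n, alpha),
       n = n)
}

#' Cross-validated word-behavior decoding with optional intent removal
#'
#' Fits a Gaussian naive Bayes classifier over all word-behavior
#' combinations with stratified k-fold cross-validation, optionally
#' removing the motor-intent dimension. The direction is refit on each
#' training fold and applied to both the training and the held-out trials,
#' so removal never uses test data.
#'
#' @param fvs a [feature_set()] with two behaviors.
#' @param remove_intent project out the motor-intent dimension (default
#'   `FALSE`).
#' @param k number of folds (default 10).
#' @param seed integer seed for fold assignment.
#' @param attempted,inner behavior labels passed to [fit_motor_intent()].
#' @return List with the elements of [word_behavior_accuracy()] plus
#'   `condition_accuracy`, `confusion`, `predictions`.
#' @export
word_behavior_cv_decode <- function(fvs, remove_intent = FALSE, k = 10,
                                    seed = 1, attempted = "attempted",
                                    inner = "inner") {
  stopifnot(inherits(fvs, "feature_set"))
  y <- paste(fvs$word, fvs$behavior, sep = ":")
  with_seed(seed, {
    folds <- stratified_folds(y, k)
    pred <- character(length(y))
    for (f in seq_len(k)) {
      tr <- folds != f
      train_fvs <- subset_trials(fvs, tr)
      x_train <- train_fvs$vectors
      x_test <- fvs$vectors[!tr, , drop = FALSE]
      if (remove_intent) {
        mi <- fit_motor_intent(train_fvs, attempted, inner)
        x_train <- remove_motor_intent(x_train, mi)
        x_test <- remove_motor_intent(x_test, mi)
      }
      m <- gnb_fit(x_train, y[tr])
      pred[!tr] <- gnb_predict(m, x_test)
    }
    split_pred <- strsplit(pred, ":", fixed = TRUE)
    pred_word <- vapply(split_pred, `[`, character(1), 1L)
    pred_behavior <- vapply(split_pred, `[`, character(1), 2L)
    res <- word_behavior_accuracy(fvs$word, fvs$behavior,
                                  pred_word, pred_behavior)
    classes <- sort(unique(y))
    res$condition_accuracy <- mean(pred == y)
    res$confusion <- table(true = factor(y, classes),
                           predicted = factor(pred, classes))
    res$predictions <- pred
    res
  })
}

#' Serialize / restore a motor-intent model as JSON
#'
#' @param model a `motor_intent_model`.
#' @param path JSON file path.
#' @return `write_motor_intent` returns `path` invisibly;
#'   `read_motor_intent` the restored model.
#' @export
write_motor_intent <- function(model, path) {
  stopifnot(inherits(model, "motor_intent_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_motor_intent
#' @export
read_motor_intent <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x[c("centroid_attempted", "centroid_inner", "direction",
                "magnitude", "behaviors")],
            class = "motor_intent_model")
}
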