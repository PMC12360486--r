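make_two_behavior_fvs <- function(offset_scale = 2, tuning_scale = 2,
                                  noise_sd = 0.5, n_per = 12, nf = 24,
                                  inner_scale = 1, seed = 41) {
  set.seed(seed)
  tun <- matrix(rnorm(7 * nf, 0, tuning_scale / sqrt(nf)), 7,
                dimnames = list(paste0("w", 1:7)))
  off <- rnorm(nf); off <- off / sqrt(sum(off^2)) * offset_scale
  means <- list(
    attempted = tun,
    inner = inner_scale * tun + rep(off, each = 7))
  fvs <- synthetic_fvs(means, n_per = n_per, noise_sd = noise_sd,
                       seed = seed + 1)
  list(fvs = fvs, offset = off, tuning = tun)
}

test_that("the fitted direction and magnitude match hand-built centroids", {
  nf <- 8
  base <- matrix(0, 2, nf, dimnames = list(c("w1", "w2")))
  shifted <- base
  shifted[, 1] <- shifted[, 1] - 2     # inner centroid displaced by (-2, 0...)
  fvs <- synthetic_fvs(list(attempted = base, inner = shifted),
                       n_per = 3, noise_sd = 0)
  mi <- fit_motor_intent(fvs)
  expect_equal(mi$direction, c(1, rep(0, nf - 1)), tolerance = 1e-12)
  expect_equal(mi$magnitude, 2, tolerance = 1e-12)
})

test_that("identical behaviors raise the degenerate-direction error", {
  nf <- 6
  m <- matrix(rnorm(2 * 6), 2, dimnames = list(c("w1", "w2")))
  fvs <- synthetic_fvs(list(attempted = m, inner = m), n_per = 3,
                       noise_sd = 0)
  expect_error(fit_motor_intent(fvs), "no separable motor-intent")
})

test_that("the fitted direction converges to the generative offset", {
  cos_sim <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  small <- make_two_behavior_fvs(n_per = 8, noise_sd = 2, seed = 42)
  big <- make_two_behavior_fvs(n_per = 400, noise_sd = 2, seed = 42)
  c_small <- cos_sim(fit_motor_intent(small$fvs)$direction, -small$offset)
  c_big <- cos_sim(fit_motor_intent(big$fvs)$direction, -big$offset)
  expect_gt(c_big, 0.98)
  expect_gt(c_big, c_small - 0.02)  # more trials, tighter alignment
})

test_that("projection removal is exact, idempotent and orthogonal", {
  model <- structure(
    list(centroid_attempted = c(1, 0), centroid_inner = c(-1, 0),
         direction = c(1, 0), magnitude = 2,
         behaviors = c(attempted = "attempted", inner = "inner")),
    class = "motor_intent_model")
  expect_equal(remove_motor_intent(matrix(c(3, 4), 1), model),
               matrix(c(0, 4), 1), tolerance = 1e-12)
  x_perp <- matrix(c(0, 7), 1)
  expect_equal(remove_motor_intent(x_perp, model), x_perp,
               tolerance = 1e-12)
  x <- matrix(rnorm(20), 10)
  once <- remove_motor_intent(x, model)
  expect_equal(remove_motor_intent(once, model), once, tolerance = 1e-12)
  expect_lt(max(abs(once %*% model$direction)), 1e-9)
  expect_error(remove_motor_intent(matrix(1, 1, 3), model),
               "dimension mismatch")
})

test_that("residuals after removal carry no refittable motor intent", {
  d <- make_two_behavior_fvs(seed = 43)
  mi <- fit_motor_intent(d$fvs)
  resid <- remove_motor_intent(d$fvs, mi)
  refit <- tryCatch(fit_motor_intent(resid), error = function(e) NULL)
  if (is.null(refit)) {
    succeed("residual centroid difference below the degeneracy threshold")
  } else {
    expect_lt(refit$magnitude, 1e-6)
  }
})

test_that("word/behavior accuracy decomposition matches its combinatorics", {
  tw <- rep(paste0("w", 1:7), each = 2)
  tb <- rep(c("attempted", "inner"), 7)
  perfect <- word_behavior_accuracy(tw, tb, tw, tb)
  expect_identical(perfect$word_accuracy, 1)
  expect_identical(perfect$behavior_accuracy, 1)

  flipped_b <- ifelse(tb == "attempted", "inner", "attempted")
  flip <- word_behavior_accuracy(tw, tb, tw, flipped_b)
  expect_identical(flip$word_accuracy, 1)
  expect_identical(flip$behavior_accuracy, 0)

  # uniform random predictions over the 14 classes: word ~ 1/7, behavior ~ 1/2
  set.seed(44)
  n <- 14000
  words <- paste0("w", 1:7)
  behs <- c("attempted", "inner")
  truth_w <- sample(words, n, TRUE); truth_b <- sample(behs, n, TRUE)
  pred_w <- sample(words, n, TRUE); pred_b <- sample(behs, n, TRUE)
  unif <- word_behavior_accuracy(truth_w, truth_b, pred_w, pred_b)
  expect_equal(unif$word_accuracy, 1 / 7, tolerance = 0.1)
  expect_equal(unif$behavior_accuracy, 1 / 2, tolerance = 0.05)
  expect_error(word_behavior_accuracy(character(0), character(0),
                                      character(0), character(0)),
               "empty")
})

test_that("removing the motor-intent dimension collapses behavior accuracy only", {
  d <- make_two_behavior_fvs(offset_scale = 2, tuning_scale = 2,
                             noise_sd = 0.4, n_per = 16, seed = 45)
  before <- word_behavior_cv_decode(d$fvs, remove_intent = FALSE, seed = 46)
  after <- word_behavior_cv_decode(d$fvs, remove_intent = TRUE, seed = 46)
  expect_gt(before$behavior_accuracy, 0.9)
  expect_lt(abs(after$behavior_accuracy - 0.5), 0.12)
  expect_lt(abs(after$word_accuracy - before$word_accuracy), 0.05)
})

test_that("within/across-behavior distances recover modulation vs offset", {
  # equal scales, offset comparable to word modulation: the across-behavior
  # matched-word distance estimates the offset magnitude, within-behavior
  # pair distances estimate word modulation
  d <- make_two_behavior_fvs(offset_scale = 3, tuning_scale = 2,
                             noise_sd = 0.5, n_per = 20, seed = 47)
  fvs <- d$fvs
  words <- paste0("w", 1:7)
  across <- vapply(words, function(w) {
    cv_distance(fvs$vectors[fvs$word == w & fvs$behavior == "attempted", ],
                fvs$vectors[fvs$word == w & fvs$behavior == "inner", ],
                n_splits = 50, seed = 48)
  }, numeric(1))
  expect_equal(mean(across), 3, tolerance = 0.15)
  wp <- word_pair_distances(fvs, "attempted", n_splits = 50, seed = 49)
  true_wp <- mean(vapply(seq_len(nrow(wp)), function(i)
    sqrt(sum((d$tuning[wp$word_i[i], ] - d$tuning[wp$word_j[i], ])^2)),
    numeric(1)))
  expect_equal(mean(wp$distance), true_wp, tolerance = 0.15)
})

test_that("motor-intent models serialize losslessly to JSON", {
  d <- make_two_behavior_fvs(seed = 50)
  mi <- fit_motor_intent(d$fvs)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_motor_intent(mi, path)
  back <- read_motor_intent(path)
  expect_equal(back$direction, mi$direction, tolerance = 1e-12)
  expect_equal(back$magnitude, mi$magnitude, tolerance = 1e-12)
  expect_equal(sqrt(sum(back$direction^2)), 1, tolerance = 1e-9)
})
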