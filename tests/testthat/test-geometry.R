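test_that("cv_distance is exact on noiseless conditions and ~0 under the null", {
  a <- matrix(rep(c(1, 2, 3), each = 6), 6)
  b <- matrix(rep(c(4, 0, 3), each = 6), 6)
  expect_equal(cv_distance(a, b, n_splits = 5, seed = 1),
               sqrt(sum(c(3, -2, 0)^2)), tolerance = 1e-12)

  set.seed(2)
  x <- matrix(rnorm(40 * 10), 40)
  y <- matrix(rnorm(40 * 10), 40)
  d <- cv_distance(x, y, n_splits = 200, seed = 3)
  # signed root keeps null estimates near zero (possibly negative)
  expect_lt(abs(d), 0.8)
  expect_error(cv_distance(x[1, , drop = FALSE], y), "at least 2")
})

test_that("cv_distance is unbiased where the plug-in overestimates", {
  # Poisson observations around two mean patterns 2.0 apart
  mu_a <- rep(4, 16)
  mu_b <- mu_a + 2 / sqrt(16)
  true_d <- 2
  set.seed(4)
  reps <- 200
  est <- naive <- numeric(reps)
  for (r in seq_len(reps)) {
    a <- matrix(rpois(100 * 16, mu_a), 100, byrow = TRUE)
    b <- matrix(rpois(100 * 16, mu_b), 100, byrow = TRUE)
    est[r] <- cv_distance(a, b, n_splits = 30, seed = r)
    naive[r] <- sqrt(sum((colMeans(a) - colMeans(b))^2))
  }
  expect_lt(abs(mean(est) - true_d) / true_d, 0.05)
  expect_gt(mean(naive), mean(est))
  expect_gt(mean(naive), true_d * 1.05)
})

test_that("cv_correlation is scale-invariant and zero for orthogonal patterns", {
  pat <- c(3, -1, 2, 0, 1)
  a <- matrix(rep(pat, each = 8), 8)
  b <- matrix(rep(0.5 * pat, each = 8), 8)
  expect_equal(cv_correlation(a, b, n_splits = 10, seed = 1), 1,
               tolerance = 1e-9)

  orth <- c(1, 3, 0, 5, 0)  # orthogonal to pat
  stopifnot(sum(pat * orth) == 0)
  b2 <- matrix(rep(orth, each = 8), 8)
  expect_equal(cv_correlation(a, b2, n_splits = 10, seed = 1), 0,
               tolerance = 1e-12)
})

test_that("cv_correlation centers near 1 for weak matched patterns, naive below", {
  set.seed(5)
  pat <- rnorm(12)
  reps <- 150
  cv_est <- naive_est <- numeric(reps)
  for (r in seq_len(reps)) {
    a <- matrix(rep(pat, each = 12), 12) + matrix(rnorm(144, 0, 1.5), 12)
    b <- matrix(rep(2 * pat, each = 12), 12) + matrix(rnorm(144, 0, 1.5), 12)
    cv_est[r] <- cv_correlation(a, b, n_splits = 30, seed = r)
    naive_est[r] <- cor(colMeans(a), colMeans(b))
  }
  cv_est <- cv_est[is.finite(cv_est)]
  expect_lt(abs(median(cv_est) - 1), 0.15)
  expect_gt(sum(cv_est > 1), 0)        # excursions beyond 1 do occur
  expect_lt(mean(naive_est), 0.95)     # the plug-in is shrunk toward 0
  expect_lt(mean(naive_est), mean(cv_est))
})

test_that("nonpositive cross-validated magnitudes are flagged, not faked", {
  # two trials that are exact negatives: every half-split self inner
  # product is -||v||^2 < 0, so the magnitude estimate must be rejected
  v <- c(2, -1, 3)
  a <- rbind(v, -v)
  b <- matrix(rep(c(1, 1, 1), each = 4), 4)
  expect_warning(got <- cv_correlation(a, b, n_splits = 5, seed = 6),
                 "nonpositive")
  expect_true(is.nan(got))
})

test_that("normalized distances recover the generator's behavior scale", {
  m <- build_population_model(
    list(n_features = 48, tuning_sd = 0.6, drift_sd = 0,
         behavior_scales = c(attempted = 1, inner = 0.5)), seed = 7)
  tr <- tiny_trials(m, behaviors = c("attempted", "inner"), n_reps = 25,
                    schedule = "interleaved", n_blocks = 2, seed = 8)
  fv <- window_average(smooth_and_normalize(tr), 0, 500)
  nd <- normalized_distances(fv, "attempted", n_splits = 60, seed = 9)
  expect_identical(nd$normalized[nd$behavior == "attempted"], 1)
  expect_equal(nd$normalized[nd$behavior == "inner"], 0.5,
               tolerance = 0.12)
  expect_identical(nd$n_pairs, rep(21L, 2))
})

test_that("a zero-tuning behavior normalizes to ~0", {
  m <- build_population_model(
    list(n_features = 32, tuning_sd = 0.6, drift_sd = 0,
         behavior_scales = c(attempted = 1, rest = 0)), seed = 10)
  tr <- tiny_trials(m, behaviors = c("attempted", "rest"), n_reps = 15,
                    schedule = "interleaved", n_blocks = 2, seed = 11)
  fv <- window_average(smooth_and_normalize(tr), 0, 500)
  nd <- normalized_distances(fv, "attempted", n_splits = 40, seed = 12)
  expect_lt(abs(nd$normalized[nd$behavior == "rest"]), 0.15)
})

test_that("PCA word rings satisfy subspace and reconstruction identities", {
  set.seed(13)
  basis <- qr.Q(qr(matrix(rnorm(20 * 3), 20)))  # random 3-D subspace
  coords <- matrix(rnorm(7 * 3, 0, 2), 7)
  means <- coords %*% t(basis)
  rownames(means) <- paste0("att:w", 1:7)
  rings <- pca_word_rings(means)
  expect_equal(sum(rings$explained), 1, tolerance = 1e-9)

  # reconstruction from the top components recovers the centered data
  centered <- scale(means, scale = FALSE)
  recon <- rings$projections %*% t(rings$fit$rotation[, 1:3])
  expect_equal(recon, centered, tolerance = 1e-9, ignore_attr = TRUE)

  # rank-deficient input degrades gracefully
  flat <- means[1:3, ]
  expect_warning(r2 <- pca_word_rings(flat), "rank")
  expect_lte(ncol(r2$projections), 2)
})

test_that("shared tuning plus an offset yields congruent, separated rings", {
  set.seed(14)
  nf <- 30
  tun <- matrix(rnorm(7 * nf), 7)
  offset <- rnorm(nf); offset <- offset / sqrt(sum(offset^2)) * 4
  att <- tun
  inn <- 0.5 * tun + rep(offset, each = 7)
  means <- rbind(att, inn)
  rownames(means) <- c(paste0("att:w", 1:7), paste0("inn:w", 1:7))
  rings <- pca_word_rings(means)
  p <- rings$projections
  att_ring <- p[1:7, ] ; inn_ring <- p[8:14, ]
  # congruent up to scale: centered rings correlate strongly
  ca <- scale(att_ring, scale = FALSE); ci <- scale(inn_ring, scale = FALSE)
  expect_gt(abs(cor(as.numeric(ca), as.numeric(ci))), 0.95)
  # separated: centroid distance in PC space is comparable to the offset
  expect_gt(sqrt(sum((colMeans(att_ring) - colMeans(inn_ring))^2)), 2)
})

test_that("behavior vectors concatenate per-word patterns for correlation", {
  set.seed(15)
  nf <- 6L
  tun <- matrix(rnorm(3 * nf), 3, dimnames = list(c("bat", "day", "kite")))
  means <- list(attempted = tun, inner = 0.5 * tun)
  fvs <- synthetic_fvs(means, n_per = 12, noise_sd = 0.3, seed = 15)
  fvs <- subtract_word_mean(fvs)
  bva <- behavior_vectors(fvs, "attempted")
  bvi <- behavior_vectors(fvs, "inner")
  expect_identical(ncol(bva), 3L * nf)
  r <- cv_correlation(bva, bvi, n_splits = 50, seed = 16)
  expect_gt(r, 0.8)
})
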