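test_that("population models are deterministic and validate their inputs", {
  a <- build_population_model(list(n_features = 16), seed = 7)
  b <- build_population_model(list(n_features = 16), seed = 7)
  expect_identical(a, b)
  c <- build_population_model(list(n_features = 16), seed = 8)
  expect_false(identical(a$tuning, c$tuning))

  m <- build_population_model(
    list(behavior_scales = c(attempted = 1, inner = 0.5)), seed = 1)
  expect_identical(m$behavior_scales[["inner"]], 0.5)

  z <- build_population_model(list(tuning_sd = 0, n_features = 8), seed = 1)
  expect_true(all(z$tuning == 0))

  expect_error(build_population_model(
    list(behavior_scales = c(attempted = 1, inner = 1.2)), seed = 1),
    "\\[0, 1\\]")
  expect_error(build_population_model(
    list(behavior_scales = c(attempted = 0.9, inner = 0.5)), seed = 1),
    "fixed at 1")
  expect_error(build_population_model(
    list(word_durations_ms = c(-1, rep(400, 6))), seed = 1), "positive")
})

test_that("noiseless, untuned, drift-free trials sit exactly at baseline", {
  m <- tiny_model(tuning_sd = 0)
  tr <- tiny_trials(m, n_reps = 2)
  for (f in seq_len(m$n_features)) {
    expect_equal(as.numeric(tr$features[, , f]),
                 rep(m$baseline[f], prod(dim(tr)[1:2])))
  }
})

test_that("noiseless go-epoch plateau matches the analytic condition mean", {
  m <- tiny_model(behavior_scales = c(attempted = 1, inner = 0.4),
                  offset_magnitude = c(attempted = 0, inner = 1))
  tr <- suppressWarnings(
    tiny_trials(m, behaviors = c("attempted", "inner"), n_reps = 1))
  # plateau bins: past latency + rise, before duration end, for every word
  for (i in seq_len(dim(tr)[1])) {
    t_ms <- (seq_len(dim(tr)[2]) - tr$go_bin[i]) * tr$bin_ms
    plateau <- t_ms >= m$latency_ms + m$rise_ms + tr$bin_ms &
      t_ms <= m$latency_ms + m$rise_ms +
        m$word_durations_ms[[tr$word[i]]] - tr$bin_ms
    # negative expected rates are clipped by the simulator
    want <- pmax(expected_go_rate(m, tr$word[i], tr$behavior[i]), 0)
    for (b in which(plateau)) {
      expect_equal(unname(tr$features[i, b, ]), unname(want),
                   tolerance = 1e-12)
    }
  }
})

test_that("empirical condition means converge to the analytic oracle", {
  m <- build_population_model(
    list(words = c("bat", "day"), n_features = 6, tuning_sd = 0.4,
         drift_sd = 0),
    seed = 3)
  n <- 2000
  sched <- data.frame(word = rep("bat", n), behavior = "attempted",
                      block = "b1")
  tr <- simulate_trials(m, sched, seed = 5, n_delay_bins = 2,
                        n_go_bins = 40)
  # average the plateau window across many trials of one condition
  t_ms <- (seq_len(dim(tr)[2]) - tr$go_bin[1]) * tr$bin_ms
  sel <- t_ms >= 400 & t_ms < 700
  emp <- colMeans(apply(tr$features[, sel, , drop = FALSE], c(1, 3), mean))
  want <- pmax(expected_go_rate(m, "bat", "attempted"), 0)
  se <- apply(apply(tr$features[, sel, , drop = FALSE], c(1, 3), mean),
              2, sd) / sqrt(n)
  expect_true(all(abs(emp - want) < 3 * se + 1e-9))
})

test_that("within-block behavior contrasts are unbiased under drift", {
  m <- build_population_model(
    list(words = c("bat", "day"), n_features = 6, tuning_sd = 0,
         behavior_scales = c(attempted = 1, inner = 1),
         offset_magnitude = c(attempted = 0, inner = 2),
         drift_sd = 1.5),
    seed = 9)
  sched <- make_schedule(m$words, c("attempted", "inner"), n_reps = 300,
                         schedule = "interleaved", n_blocks = 3, seed = 2)
  tr <- suppressWarnings(simulate_trials(m, sched, seed = 4))
  fv <- window_average(smooth_and_normalize(tr, sigma_ms = 0,
                                            do_std = FALSE), 400, 300)
  # per block, the attempted-minus-inner mean estimates -offset_inner
  # regardless of the block's drift
  offset <- m$behavior_offsets["inner", ]
  for (b in unique(fv$block)) {
    idx <- fv$block == b
    delta <- colMeans(fv$vectors[idx & fv$behavior == "inner", ]) -
      colMeans(fv$vectors[idx & fv$behavior == "attempted", ])
    expect_lt(sqrt(sum((delta - offset)^2)) / sqrt(sum(offset^2)), 0.25)
  }
})

test_that("blocked drift shows up across blocks at the configured scale", {
  m <- build_population_model(
    list(words = c("bat", "day"), n_features = 40, tuning_sd = 0,
         drift_sd = 1, noise = "none"),
    seed = 13)
  sched <- make_schedule(m$words, "attempted", n_reps = 20,
                         schedule = "blocked", n_blocks = 10, seed = 3)
  tr <- suppressWarnings(simulate_trials(m, sched, seed = 6))
  fv <- window_average(tr, -400, 300)  # delay epoch: baseline + drift only
  block_means <- t(vapply(unique(fv$block), function(b)
    colMeans(fv$vectors[fv$block == b, , drop = FALSE]),
    numeric(ncol(fv$vectors))))
  # SD of block means around the baseline estimates drift_sd
  est <- sqrt(mean((sweep(block_means, 2, m$baseline))^2))
  expect_gt(est, 0.6)
  expect_lt(est, 1.4)
})

test_that("counting decodes follow the ascent model", {
  up <- simulate_counting_decodes(3, length_range = c(5, 5),
                                  ascent_prob = 1, seed = 1)
  expect_identical(up[[1]], 1:5)
  expect_identical(up[[2]], 1:5)

  flat <- simulate_counting_decodes(400, length_range = c(6, 6),
                                    ascent_prob = 0, vocab_max = 20,
                                    seed = 2)
  vals <- do.call(rbind, flat)
  expect_equal(mean(vals), (1 + 20) / 2, tolerance = 0.05 * 10.5)
  expect_lt(abs(counting_slope(flat)$slope), 0.15)

  expect_identical(simulate_counting_decodes(5, seed = 3),
                   simulate_counting_decodes(5, seed = 3))
  expect_error(simulate_counting_decodes(2, length_range = c(5, 2)),
               "length_range")
  expect_error(simulate_counting_decodes(2, ascent_prob = 1.5),
               "ascent_prob")
})

test_that("logit pairs warp and flag as documented", {
  tmpl <- simulate_logit_template(40, seed = 5)
  same <- simulate_logit_pair(tmpl, stretch = 1, noise_sd = 0, seed = 1)
  expect_equal(unname(same$b[, ]), unname(tmpl[, ]), tolerance = 1e-12)
  expect_true(attr(same, "band_ok"))

  pair <- simulate_logit_pair(tmpl, stretch = 1.05, noise_sd = 0, seed = 1)
  expect_equal(nrow(pair$b), 42)
  expect_error(simulate_logit_pair(tmpl, stretch = -1), "positive")
})

test_that("sessions round-trip through the plain-text bundle", {
  tr <- tiny_trials(n_reps = 2)
  path <- file.path(tempdir(), "session-roundtrip")
  on.exit(unlink(path, recursive = TRUE))
  write_session(tr, path)
  back <- read_session(path)
  expect_equal(back$features, tr$features, tolerance = 1e-12)
  expect_identical(back$word, tr$word)
  expect_identical(back$behavior, tr$behavior)
  expect_identical(back$block, tr$block)
  expect_identical(back$go_bin, tr$go_bin)
  expect_identical(back$bin_ms, tr$bin_ms)
  expect_identical(back$schedule, tr$schedule)
})
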