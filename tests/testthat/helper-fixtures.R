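# Small builders shared across test files. Everything is generated in code;
# sizes are kept small so the default run stays fast.

tiny_model <- function(..., seed = 11) {
  build_population_model(utils::modifyList(list(
    words = c("bat", "day", "kite"),
    n_features = 8,
    tuning_sd = 0.5,
    drift_sd = 0,
    noise = "none"), list(...)), seed = seed)
}

tiny_trials <- function(model = tiny_model(), behaviors = "attempted",
                        n_reps = 4, schedule = "blocked", seed = 21,
                        n_blocks = 2, ...) {
  sched <- make_schedule(model$words, behaviors, n_reps = n_reps,
                         schedule = schedule, n_blocks = n_blocks,
                         seed = seed)
  # clip warnings are expected when tuning dips below a small baseline
  suppressWarnings(simulate_trials(model, sched, seed = seed + 1, ...))
}

# feature_set with exactly specified per-condition means + gaussian noise
synthetic_fvs <- function(means, n_per = 10, noise_sd = 0, seed = 31) {
  # means: named list behavior -> (word x feature matrix with rownames)
  vectors <- NULL; word <- character(0); behavior <- character(0)
  set.seed(seed)
  for (b in names(means)) {
    m <- means[[b]]
    for (w in rownames(m)) {
      x <- matrix(rep(m[w, ], each = n_per), n_per) +
        matrix(rnorm(n_per * ncol(m), 0, noise_sd), n_per)
      vectors <- rbind(vectors, x)
      word <- c(word, rep(w, n_per))
      behavior <- c(behavior, rep(b, n_per))
    }
  }
  feature_set(vectors, word, behavior, block = rep("b1", length(word)))
}
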