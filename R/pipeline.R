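#' Default pipeline configuration
#'
#' Returns the configuration driving [run_pipeline()]: generator
#' settings, per-stage toggles, fold/bootstrap counts and per-stage
#' seeds. Every stochastic stage has its own named seed derived from the
#' master `seed` so stages can be toggled without changing each other's
#' draws. The configuration round-trips unchanged through YAML or JSON.
#'
#' @param seed master integer seed.
#' @return Nested named list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    generator = list(
      n_features = 64,
      tuning_sd = 0.35,
      inner_scale = 0.5,
      offset_magnitude = 2,
      drift_sd = 0.2,
      n_reps = 20,
      n_blocks = 4),
    stages = list(
      decode = TRUE, geometry = TRUE, intent = TRUE,
      sequences = TRUE, counting = TRUE, wer = TRUE, dtw = TRUE),
    decode = list(candidate_starts = c(0, 200), window_ms = 500,
                  k_outer = 10, k_inner = 10),
    geometry = list(n_splits = 50),
    sequences = list(n_per_seq = 20, n_boot = 2000),
    counting = list(n_trials = 40, ascent_prob = 0.9, n_resamples = 200),
    wer = list(n_boot = 2000, n_shuffles = 2000),
    dtw = list(stretch = 1.05, noise_sd = 0.05, band_ms = 100))
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return Configuration list merged over [default_config()].
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  utils::modifyList(default_config(), cfg)
}

#' Run the full synthetic-session analysis pipeline
#'
#' Simulates sessions from the generator, preprocesses them, and executes
#' the toggled analysis stages: nested-CV word decoding, normalized
#' distance geometry, motor-intent fitting/removal with word-vs-behavior
#' accuracy, position-wise sequence decoding, counting-slope inference
#' with the stitched null, aggregate WER with permutation chance, and the
#' DTW logit correlation. One result table per stage is written to
#' `out_dir` as CSV plus a machine-readable `summary.json` and a run log
#' recording seeds. A failing stage aborts with its name; tables written
#' before the failure are retained.
#'
#' @param config list from [default_config()] or [read_config()].
#' @param out_dir output directory (created if needed).
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  seed <- config$seed
  gen <- config$generator
  summ <- list(
    package_version = as.character(utils::packageVersion("innerspeech")),
    seed = seed,
    generator = gen)
  logf("pipeline start (seed %d)", seed)

  model <- build_population_model(
    config = list(
      n_features = gen$n_features, tuning_sd = gen$tuning_sd,
      behavior_scales = c(attempted = 1, inner = gen$inner_scale),
      offset_magnitude = c(attempted = 0, inner = gen$offset_magnitude),
      drift_sd = gen$drift_sd),
    seed = seed)

  sched <- make_schedule(model$words, c("attempted", "inner"),
                         n_reps = gen$n_reps, schedule = "interleaved",
                         n_blocks = gen$n_blocks, seed = seed + 1)
  trials <- suppressWarnings(simulate_trials(model, sched, seed = seed + 2))
  trials <- smooth_and_normalize(trials)
  fvs <- window_average(trials, start_ms = 0, length_ms = 500)
  logf("simulated %d trials", n_trials(trials))

  st <- config$stages

  if (isTRUE(st$decode)) run_stage("decode", {
    att <- window_trials_subset(trials, trials$behavior == "attempted")
    res <- nested_cv_gnb(att, config$decode$candidate_starts,
                         window_ms = config$decode$window_ms,
                         k_outer = config$decode$k_outer,
                         k_inner = config$decode$k_inner, seed = seed + 3)
    write.csv(as.data.frame(res$confusion),
              file.path(out_dir, "decode_confusion.csv"), row.names = FALSE)
    summ$decode <- list(accuracy = res$accuracy, ci_low = res$ci$low,
                            ci_high = res$ci$high, chance = res$chance,
                            significant = res$significant,
                            chosen_windows = res$chosen_window_per_fold)
    logf("decode: accuracy %.3f", res$accuracy)
  })

  if (isTRUE(st$geometry)) run_stage("geometry", {
    nd <- normalized_distances(fvs, "attempted",
                               n_splits = config$geometry$n_splits,
                               seed = seed + 4)
    write.csv(nd, file.path(out_dir, "normalized_distances.csv"),
              row.names = FALSE)
    rings <- pca_word_rings(condition_means(fvs))
    write.csv(data.frame(condition = rownames(rings$projections),
                         rings$projections),
              file.path(out_dir, "pca_projections.csv"), row.names = FALSE)
    summ$geometry <- list(
      normalized = setNames(as.list(nd$normalized), nd$behavior),
      pca_explained = rings$explained)
    logf("geometry: inner/attempted distance ratio %.3f",
         nd$normalized[nd$behavior == "inner"])
  })

  if (isTRUE(st$intent)) run_stage("intent", {
    mi <- fit_motor_intent(fvs)
    write_motor_intent(mi, file.path(out_dir, "motor_intent.json"))
    before <- word_behavior_cv_decode(fvs, remove_intent = FALSE,
                                      seed = seed + 5)
    after <- word_behavior_cv_decode(fvs, remove_intent = TRUE,
                                     seed = seed + 5)
    write.csv(as.data.frame(before$confusion),
              file.path(out_dir, "intent_confusion_before.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(after$confusion),
              file.path(out_dir, "intent_confusion_after.csv"),
              row.names = FALSE)
    summ$intent <- list(
      magnitude = mi$magnitude,
      word_accuracy_before = before$word_accuracy,
      word_accuracy_after = after$word_accuracy,
      behavior_accuracy_before = before$behavior_accuracy,
      behavior_accuracy_after = after$behavior_accuracy)
    logf("intent: behavior accuracy %.3f -> %.3f",
         before$behavior_accuracy, after$behavior_accuracy)
  })

  if (isTRUE(st$sequences)) run_stage("sequences", {
    sq <- config$sequences
    tset <- simulate_sequence_trials(sq$n_per_seq, signal_positions = 1,
                                     strategy = "verbal", seed = seed + 6)
    rows <- lapply(seq_len(ncol(tset$sequences)), function(p) {
      r <- positionwise_pair_decode(tset, p, seed = seed + 6 + p)
      ci <- bootstrap_ci_positions(r, n_boot = sq$n_boot, seed = seed + 16 + p)
      data.frame(position = p, accuracy = r$pooled_accuracy,
                 ci_low = ci$ci[1], ci_high = ci$ci[2],
                 significant = ci$significant)
    })
    tab <- do.call(rbind, rows)
    write.csv(tab, file.path(out_dir, "sequence_positions.csv"),
              row.names = FALSE)
    summ$sequences <- list(accuracy = tab$accuracy,
                               significant = tab$significant)
    logf("sequences: position accuracies %s",
         paste(sprintf("%.2f", tab$accuracy), collapse = " "))
  })

  if (isTRUE(st$counting)) run_stage("counting", {
    cc <- config$counting
    seqs <- simulate_counting_decodes(cc$n_trials,
                                      ascent_prob = cc$ascent_prob,
                                      seed = seed + 7)
    sl <- counting_slope(seqs)
    controls <- simulate_counting_decodes(60, ascent_prob = 0,
                                          length_range = c(4, 8),
                                          seed = seed + 8)
    nullres <- stitched_null(controls, n_trials = cc$n_trials,
                             n_resamples = cc$n_resamples, seed = seed + 9,
                             observed_slope = sl$slope)
    write.csv(data.frame(null_slope = nullres$null_slopes),
              file.path(out_dir, "counting_null_slopes.csv"),
              row.names = FALSE)
    summ$counting <- list(slope = sl$slope, p = sl$p_two_tailed,
                              null_percentile = nullres$percentile)
    logf("counting: slope %.3f (p = %.2g)", sl$slope, sl$p_two_tailed)
  })

  if (isTRUE(st$wer)) run_stage("wer", {
    ref <- c("i need good music", "how are you today",
             "the weather is nice", "please bring water",
             "counting is hard work", "speech can be imagined")
    dec <- c("i need good music", "how are you", "the weather was nice",
             "please bring some water", "counting is hard work",
             "speech can imagined be")
    rep_wer <- aggregate_wer(ref, dec, n_boot = config$wer$n_boot,
                             seed = seed + 10)
    chance <- shuffled_chance_wer(ref, dec,
                                  n_shuffles = config$wer$n_shuffles,
                                  seed = seed + 11)
    write.csv(rep_wer$per_sentence, file.path(out_dir, "wer_sentences.csv"),
              row.names = FALSE)
    summ$wer <- list(aggregate = rep_wer$wer,
                         ci = rep_wer$ci,
                         chance_lower_bound = chance$chance_lower_bound)
    logf("wer: %.1f%% (chance bound %.1f%%)", 100 * rep_wer$wer,
         100 * chance$chance_lower_bound)
  })

  if (isTRUE(st$dtw)) run_stage("dtw", {
    dt <- config$dtw
    template <- simulate_logit_template(40, seed = seed + 12)
    pair <- simulate_logit_pair(template, stretch = dt$stretch,
                                noise_sd = dt$noise_sd, seed = seed + 13)
    r <- dtw_logit_correlation(pair$a, pair$b, band_ms = dt$band_ms)
    summ$dtw <- list(correlation = r, band_ok = attr(pair, "band_ok"))
    logf("dtw: aligned correlation %.3f", r)
  })

  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("pipeline done")
  invisible(summ)
}

# subset a trial_set by trial index
window_trials_subset <- function(trials, idx) {
  trial_set(trials$features[idx, , , drop = FALSE], trials$bin_ms,
            trials$word[idx], trials$behavior[idx], trials$block[idx],
            trials$go_bin[idx], trials$schedule)
}
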