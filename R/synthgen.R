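#' Ground-truth generative model of a speech-tuned neural population
#'
#' Builds the generative description of a recorded array: per-feature
#' baseline activity, a per-word additive tuning matrix shared across
#' behaviors, behavior-specific modulation scales (attempted speech fixed
#' at 1, inner speech weaker), behavior-offset vectors (the ground-truth
#' motor-intent signal), word durations shaping a trapezoidal temporal
#' kernel, block-wise drift, and the observation-noise family per feature
#' (Poisson for threshold-crossing counts, mean-matched lognormal for
#' spike-band power).
#'
#' @param config named list overriding defaults; recognized entries:
#'   \describe{
#'     \item{words}{character vector of word labels (default 7 short words).}
#'     \item{word_durations_ms}{positive numeric per word.}
#'     \item{n_features}{feature count (default 128: 64 count + 64 power).}
#'     \item{baseline_range}{range of uniform per-feature baseline expected
#'       counts per bin (default `c(0.5, 3)`).}
#'     \item{tuning_sd}{SD of i.i.d. Gaussian per-word modulation entries
#'       (counts/bin; default 0.35).}
#'     \item{behavior_scales}{named numeric in `[0, 1]`; `attempted` must be
#'       1 (default `c(attempted = 1, inner = 0.5)`).}
#'     \item{offset_magnitude}{named numeric: Euclidean norm of each
#'       behavior's offset vector (default attempted 0, inner 0; set to the
#'       word-modulation scale to emulate a motor-intent signal).}
#'     \item{latency_ms, rise_ms}{temporal-kernel onset latency and linear
#'       rise time (defaults 200 and 150 ms).}
#'     \item{drift_sd}{SD of block-constant per-feature drift (default 0.2).}
#'     \item{power_cv}{coefficient of variation of lognormal power noise
#'       (default 0.3).}
#'     \item{noise}{`"family"` (Poisson/lognormal per feature family) or
#'       `"none"` for noiseless expected values.}
#'   }
#' @param seed integer seed; the model is deterministic given
#'   `(config, seed)`.
#' @return An object of class `population_model`.
#' @export
build_population_model <- function(config = list(), seed = 1) {
  defaults <- list(
    words = c("bat", "though", "were", "day", "kite", "ban", "choice"),
    word_durations_ms = NULL,
    n_features = 128L,
    baseline_range = c(0.5, 3),
    tuning_sd = 0.35,
    behavior_scales = c(attempted = 1, inner = 0.5),
    offset_magnitude = NULL,
    latency_ms = 200,
    rise_ms = 150,
    drift_sd = 0.2,
    power_cv = 0.3,
    noise = "family")
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)

  n_words <- length(cfg$words)
  if (n_words < 2L) stop("need at least 2 words")
  if (cfg$n_features < 2L) stop("need at least 2 features")
  if (is.null(cfg$word_durations_ms)) {
    # durations of short single-syllable cue words; "were" is the shortest
    # at 366 ms, the rest spread up to ~550 ms
    cfg$word_durations_ms <- seq(366, 550, length.out = n_words)
  }
  if (length(cfg$word_durations_ms) != n_words ||
      any(cfg$word_durations_ms <= 0)) {
    stop("word_durations_ms must be positive, one per word")
  }
  scales <- cfg$behavior_scales
  if (is.null(names(scales)) || any(!nzchar(names(scales)))) {
    stop("behavior_scales must be named")
  }
  if (any(scales < 0 | scales > 1)) stop("behavior_scales must lie in [0, 1]")
  if (!"attempted" %in% names(scales) || scales[["attempted"]] != 1) {
    stop("the attempted-speech scale is fixed at 1.0")
  }
  if (is.null(cfg$offset_magnitude)) {
    cfg$offset_magnitude <- setNames(numeric(length(scales)), names(scales))
  }
  if (!setequal(names(cfg$offset_magnitude), names(scales))) {
    stop("offset_magnitude must be named like behavior_scales")
  }

  with_seed(seed, {
    baseline <- runif(cfg$n_features, cfg$baseline_range[1],
                      cfg$baseline_range[2])
    tuning <- matrix(rnorm(n_words * cfg$n_features, 0, cfg$tuning_sd),
                     nrow = n_words,
                     dimnames = list(cfg$words, NULL))
    offsets <- vapply(names(scales), function(b) {
      v <- rnorm(cfg$n_features)
      v / sqrt(sum(v^2)) * cfg$offset_magnitude[[b]]
    }, numeric(cfg$n_features))
    offsets <- t(offsets)      # behaviors x features

    half <- floor(cfg$n_features / 2)
    noise_family <- if (identical(cfg$noise, "none")) {
      rep("none", cfg$n_features)
    } else {
      c(rep("poisson", half), rep("lognormal", cfg$n_features - half))
    }

    structure(
      list(words = cfg$words, n_features = as.integer(cfg$n_features),
           baseline = baseline, tuning = tuning,
           behavior_scales = scales, behavior_offsets = offsets,
           word_durations_ms = setNames(cfg$word_durations_ms, cfg$words),
           latency_ms = cfg$latency_ms, rise_ms = cfg$rise_ms,
           drift_sd = cfg$drift_sd, power_cv = cfg$power_cv,
           noise_family = noise_family, seed = seed),
      class = "population_model")
  })
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("<population_model> %d words x %d features\n",
              length(x$words), x$n_features))
  cat(sprintf("  behaviors: %s (scales %s)\n",
              paste(names(x$behavior_scales), collapse = ", "),
              paste(format(x$behavior_scales), collapse = ", ")))
  cat(sprintf("  drift_sd %.3g | noise: %s\n", x$drift_sd,
              paste(unique(x$noise_family), collapse = "+")))
  invisible(x)
}

#' Build a per-trial schedule of (word, behavior, block)
#'
#' In a `blocked` schedule each block holds one behavior (the isolated-task
#' design); in an `interleaved` schedule behaviors are shuffled together
#' within every block, which is what allows behavior contrasts to survive
#' block-wise mean subtraction.
#'
#' @param words,behaviors label sets.
#' @param n_reps repetitions of each (word, behavior) condition.
#' @param schedule `"blocked"` or `"interleaved"`.
#' @param n_blocks number of blocks per behavior (blocked) or in total
#'   (interleaved).
#' @param seed integer seed for trial-order shuffling.
#' @return data frame with columns `word`, `behavior`, `block`.
#' @export
make_schedule <- function(words, behaviors, n_reps,
                          schedule = c("blocked", "interleaved"),
                          n_blocks = 2, seed = 1) {
  schedule <- match.arg(schedule)
  plan <- expand.grid(word = words, behavior = behaviors,
                      rep = seq_len(n_reps), stringsAsFactors = FALSE)
  with_seed(seed, {
    if (schedule == "blocked") {
      out <- do.call(rbind, lapply(behaviors, function(b) {
        p <- plan[plan$behavior == b, c("word", "behavior")]
        p <- p[sample(nrow(p)), ]
        # contiguous blocks: split the shuffled trial list into n_blocks runs
        p$block <- paste0(b, "-", ceiling(seq_len(nrow(p)) /
                                            ceiling(nrow(p) / n_blocks)))
        p
      }))
    } else {
      out <- plan[sample(nrow(plan)), c("word", "behavior")]
      out$block <- paste0("blk-", ceiling(seq_len(nrow(out)) /
                                            ceiling(nrow(out) / n_blocks)))
    }
    rownames(out) <- NULL
    out$schedule <- schedule
    out
  })
}

# trapezoidal response kernel sampled at bin centres of the go epoch:
# 0 until latency, linear rise over rise_ms, plateau for the word duration,
# linear fall over rise_ms
trapezoid_kernel <- function(n_go_bins, bin_ms, latency_ms, rise_ms,
                             duration_ms) {
  t <- (seq_len(n_go_bins) - 0.5) * bin_ms
  up0 <- latency_ms
  up1 <- latency_ms + rise_ms
  dn0 <- up1 + duration_ms
  dn1 <- dn0 + rise_ms
  k <- numeric(n_go_bins)
  rising <- t > up0 & t < up1
  k[rising] <- (t[rising] - up0) / rise_ms
  k[t >= up1 & t <= dn0] <- 1
  falling <- t > dn0 & t < dn1
  k[falling] <- 1 - (t[falling] - dn0) / rise_ms
  k
}

#' Simulate a trial-structured session from a population model
#'
#' Each trial has a delay epoch (baseline plus block drift) followed by a
#' go epoch in which the expected rate is
#' `baseline + scale_b * tuning_w + offset_b`, shaped in time by the
#' trapezoidal kernel. Block drift is a per-feature offset drawn once per
#' block (`Normal(0, drift_sd^2)`), constant within the block. Counts are
#' drawn per the model's noise family; negative expected rates are clipped
#' to zero with a warning.
#'
#' @param model a `population_model`.
#' @param schedule data frame from [make_schedule()] (columns `word`,
#'   `behavior`, `block`, optionally `schedule`).
#' @param seed integer seed.
#' @param n_delay_bins,n_go_bins epoch lengths in bins.
#' @param bin_ms bin width (10 or 20 ms).
#' @return A [trial_set()].
#' @export
simulate_trials <- function(model, schedule, seed = 1,
                            n_delay_bins = 25, n_go_bins = 60, bin_ms = 20) {
  stopifnot(inherits(model, "population_model"))
  if (!all(schedule$word %in% model$words)) {
    stop("schedule contains words unknown to the model")
  }
  if (!all(schedule$behavior %in% names(model$behavior_scales))) {
    stop("schedule contains behaviors unknown to the model")
  }
  n <- nrow(schedule)
  n_bins <- n_delay_bins + n_go_bins
  nf <- model$n_features
  sched_kind <- if (!is.null(schedule$schedule)) schedule$schedule[1]
                else "blocked"

  with_seed(seed, {
    blocks <- unique(schedule$block)
    drift <- matrix(rnorm(length(blocks) * nf, 0, model$drift_sd),
                    nrow = length(blocks), dimnames = list(blocks, NULL))

    kernels <- lapply(model$words, function(w) {
      trapezoid_kernel(n_go_bins, bin_ms, model$latency_ms, model$rise_ms,
                       model$word_durations_ms[[w]])
    })
    names(kernels) <- model$words

    features <- array(0, dim = c(n, n_bins, nf))
    clipped <- FALSE
    for (i in seq_len(n)) {
      w <- schedule$word[i]; b <- schedule$behavior[i]
      mod <- model$behavior_scales[[b]] * model$tuning[w, ] +
        model$behavior_offsets[b, ]
      base <- model$baseline + drift[schedule$block[i], ]
      lam <- matrix(rep(base, each = n_bins), nrow = n_bins)
      lam[(n_delay_bins + 1):n_bins, ] <- lam[(n_delay_bins + 1):n_bins, ] +
        outer(kernels[[w]], mod)
      if (any(lam < 0)) { clipped <- TRUE; lam[lam < 0] <- 0 }
      features[i, , ] <- sample_observations(lam, model)
    }
    if (clipped) {
      warning("negative expected rates clipped to 0", call. = FALSE)
    }
    trial_set(features, bin_ms,
              word = schedule$word, behavior = schedule$behavior,
              block = schedule$block, go_bin = n_delay_bins + 1,
              schedule = sched_kind)
  })
}

# draw one trial's observations (bins x features) given expected rates
sample_observations <- function(lam, model) {
  out <- lam
  fam <- model$noise_family
  pois <- fam == "poisson"
  if (any(pois)) {
    out[, pois] <- rpois(sum(pois) * nrow(lam), lam[, pois])
  }
  logn <- fam == "lognormal"
  if (any(logn)) {
    m <- lam[, logn]
    sdlog <- sqrt(log(1 + model$power_cv^2))
    pos <- m > 0
    draw <- m
    draw[pos] <- rlnorm(sum(pos), log(m[pos]) - sdlog^2 / 2, sdlog)
    out[, logn] <- draw
  }
  out
}

#' Analytic expected go-epoch rate for a condition
#'
#' The noiseless expected feature vector during the kernel plateau for a
#' given word and behavior (no drift): `baseline + scale_b * tuning_w +
#' offset_b`. Used as the oracle for mean-convergence checks.
#'
#' @param model a `population_model`.
#' @param word,behavior condition labels.
#' @return Numeric vector of length `n_features`.
#' @export
expected_go_rate <- function(model, word, behavior) {
  model$baseline + model$behavior_scales[[behavior]] * model$tuning[word, ] +
    model$behavior_offsets[behavior, ]
}

#' Simulate decoded number sequences from a counting task
#'
#' Emulates the output of a number-word decoder applied to silent counting:
#' with probability `ascent_prob` a decoded value continues the ascending
#' count (position 1 starts at 1), otherwise it is resampled uniformly from
#' `1..vocab_max`. Values are capped at `vocab_max`.
#'
#' @param n_trials number of counting trials.
#' @param length_range integer `(min, max)` sequence length.
#' @param ascent_prob probability of continuing the count at each position.
#' @param vocab_max largest number word in the decoder vocabulary.
#' @param seed integer seed.
#' @return List of integer vectors.
#' @export
simulate_counting_decodes <- function(n_trials, length_range = c(10, 20),
                                      ascent_prob = 0.9, vocab_max = 20,
                                      seed = 1) {
  if (ascent_prob < 0 || ascent_prob > 1) stop("ascent_prob must be in [0, 1]")
  if (length(length_range) != 2 || length_range[1] > length_range[2] ||
      length_range[1] < 1) {
    stop("invalid length_range")
  }
  vocab_max <- as.integer(vocab_max)
  with_seed(seed, {
    lens <- length_range[1]:length_range[2]
    lapply(seq_len(n_trials), function(i) {
      len <- lens[sample.int(length(lens), 1)]
      x <- integer(len)
      for (p in seq_len(len)) {
        ascend <- runif(1) < ascent_prob
        x[p] <- if (p == 1L) {
          if (ascend) 1L else sample.int(vocab_max, 1)
        } else if (ascend) {
          min(x[p - 1L] + 1L, vocab_max)
        } else {
          sample.int(vocab_max, 1)
        }
      }
      x
    })
  })
}

#' Smooth random phoneme-logit template
#'
#' Generates a random multivariate time series shaped like decoder logit
#' output: 39 phoneme dimensions plus one silence dimension, one row per
#' 80 ms bin, temporally smoothed so that time warping is meaningful.
#'
#' @param n_bins number of 80 ms time bins.
#' @param n_dims number of output dimensions (default 40).
#' @param smooth_bins SD (in bins) of the Gaussian used to smooth white
#'   noise in time.
#' @param bin_ms bin width (default 80).
#' @param seed integer seed.
#' @return Matrix `n_bins x n_dims` with attribute `bin_ms`.
#' @export
simulate_logit_template <- function(n_bins, n_dims = 40, smooth_bins = 2,
                                    bin_ms = 80, seed = 1) {
  with_seed(seed, {
    x <- matrix(rnorm(n_bins * n_dims), n_bins, n_dims)
    if (smooth_bins > 0) {
      half <- ceiling(4 * smooth_bins)
      k <- exp(-((-half):half)^2 / (2 * smooth_bins^2))
      k <- k / sum(k)
      x <- apply(x, 2, function(col) {
        padded <- c(rep(col[1], half), col, rep(col[n_bins], half))
        stats::filter(padded, k, sides = 2)[(half + 1):(half + n_bins)]
      })
    }
    structure(x, bin_ms = bin_ms)
  })
}

#' Simulate a time-warped, noisy copy of a logit series
#'
#' The second series is the template uniformly resampled in time by
#' `stretch` (linear interpolation) plus i.i.d. Gaussian noise, emulating a
#' paired trial spoken at a different rate. The attribute `band_ok` on the
#' returned pair records whether the true (uniform) alignment stays within
#' a slanted band of half-width `band_ms` around the diagonal.
#'
#' @param template matrix from [simulate_logit_template()].
#' @param stretch positive time-stretch factor.
#' @param noise_sd SD of additive Gaussian noise.
#' @param seed integer seed.
#' @param band_ms slanted-band half-width used for the feasibility flag.
#' @return List with elements `a` (the template) and `b` (warped copy);
#'   attribute `band_ok`.
#' @export
simulate_logit_pair <- function(template, stretch = 1, noise_sd = 0,
                                seed = 1, band_ms = 100) {
  if (stretch <= 0) stop("stretch must be positive")
  n <- nrow(template)
  bin_ms <- attr(template, "bin_ms")
  if (is.null(bin_ms)) bin_ms <- 80
  m <- max(2L, round(n * stretch))
  src <- seq(1, n, length.out = m)
  b <- apply(template, 2, function(col) approx(seq_len(n), col, src)$y)
  b <- with_seed(seed, b + matrix(rnorm(m * ncol(template), 0, noise_sd),
                                  m, ncol(template)))
  attr(b, "bin_ms") <- bin_ms
  # true correspondence of b-row j is a-row src[j]; the slanted band is
  # centred on the line i = j * n/m
  dev_bins <- max(abs(src - seq_len(m) * n / m))
  structure(list(a = template, b = b),
            band_ok = dev_bins <= band_ms / bin_ms)
}

#' Simulate window-summed features for a sequence-memory task
#'
#' Generates per-trial preparatory-activity vectors for an instructed-delay
#' sequence task: every sequence over `symbols` of length `n_positions` is
#' a condition, and features carry additive tuning to symbol identity at
#' the positions listed in `signal_positions` (no tuning elsewhere), plus
#' Gaussian noise on a positive baseline.
#'
#' @param n_per_seq trials per sequence condition.
#' @param symbols direction symbols (default up/right).
#' @param n_positions sequence length (default 3).
#' @param signal_positions integer positions whose identity is encoded
#'   (possibly empty for a pure-noise task).
#' @param effect Euclidean norm of each symbol-at-position tuning vector.
#' @param noise_sd per-feature Gaussian noise SD.
#' @param n_features feature count (default 64).
#' @param strategy,task labels stored on the result.
#' @param seed integer seed.
#' @return A [sequence_trial_set()].
#' @export
simulate_sequence_trials <- function(n_per_seq, symbols = c("U", "R"),
                                     n_positions = 3, signal_positions = 1,
                                     effect = 1.5, noise_sd = 1,
                                     n_features = 64,
                                     strategy = "none", task = "arrows",
                                     seed = 1) {
  seqs <- as.matrix(expand.grid(rep(list(symbols), n_positions),
                                stringsAsFactors = FALSE))
  colnames(seqs) <- NULL
  with_seed(seed, {
    tuning <- list()
    for (p in signal_positions) {
      for (s in symbols) {
        v <- rnorm(n_features)
        tuning[[paste(p, s)]] <- v / sqrt(sum(v^2)) * effect
      }
    }
    n <- nrow(seqs) * n_per_seq
    seq_idx <- rep(seq_len(nrow(seqs)), each = n_per_seq)
    x <- matrix(rnorm(n * n_features, 0, noise_sd), n, n_features) + 20
    for (i in seq_len(n)) {
      for (p in signal_positions) {
        x[i, ] <- x[i, ] + tuning[[paste(p, seqs[seq_idx[i], p])]]
      }
    }
    x[x < 0] <- 0
    sequence_trial_set(x, seqs[seq_idx, , drop = FALSE],
                       strategy = strategy, task = task)
  })
}
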