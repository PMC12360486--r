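---
title: "Statistical methods for inner versus attempted speech analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for inner versus attempted speech analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(innerspeech)
```

## Scope and model

This package analyzes trial-structured intracortical feature arrays
(threshold-crossing counts and spike-band power, binned at 10–20 ms)
recorded while a participant attempts or imagines speaking cued words. It
starts from binned features: raw voltage filtering and reference
subtraction, recurrent-network sequence decoders and language models are
out of scope. Because real sessions of this kind are scarce, the package
ships a generator whose output has the statistical structure every
analysis assumes, so the full pipeline is exercised and tested end to end
on synthetic data.

The generative model for feature $f$, word $w$, behavior $b$, block $k$,
time bin $t$ is

$$\lambda_{f}(t) = \mathrm{baseline}_f + \mathrm{drift}_{k,f}
  + \kappa_w(t)\,\bigl(s_b\,T_{w,f} + o_{b,f}\bigr),$$

with $T$ a per-word tuning matrix shared across behaviors, $s_b \in
[0,1]$ a behavior modulation scale (attempted speech fixed at 1, inner
speech defaulting to 0.5 — half-amplitude inner speech is the regime the
analyses are designed to resolve), $o_b$ a behavior-offset vector (the
ground-truth motor-intent signal), $\mathrm{drift}_{k,f} \sim
\mathcal N(0, \sigma_d^2)$ constant within a block, and $\kappa_w$ a
trapezoidal kernel (onset latency, linear rise, plateau for the word's
duration, linear fall). Count features observe
$\mathrm{Pois}(\lambda)$; power features observe a mean-matched lognormal
with configurable coefficient of variation. Negative rates are clipped to
zero with a warning.

Choices a user should know about:

- **Noise families.** Nothing in the data dictates a generative noise
  law; Poisson for counts and mean-matched lognormal for power are the
  simplest members consistent with the two feature families, and `noise =
  "none"` gives exact expected values for oracle tests.
- **Kernel shape.** The trapezoid is the simplest shape consistent with
  peristimulus dynamics; only its integral over the decoding window
  matters to the analyses.
- **Drift.** Block-constant offsets are sufficient to exercise block-wise
  centering and the blocked-versus-interleaved design distinction; no
  within-block random walk is modelled.
- **Defaults.** 7 words, 128 features (64 + 64), word durations 366–550 ms
  (short single-syllable cue words), baseline 0.5–3 counts/bin. The
  magnitudes of tuning SD and noise are chosen for testability — the
  recordings this emulates do not publish them.

## Preprocessing

`smooth_and_normalize()` applies, in order: Gaussian temporal smoothing
(default SD 60 ms, truncated at ±4 SD, kernel renormalized to unit sum at
the edges — no padding, so edge bins keep their scale); per-block
per-feature mean subtraction (removing drift, and deliberately removing
behavior contrasts in blocked designs — which is why cross-behavior
analyses require interleaved schedules); then division by the per-feature
SD pooled over all trials and bins. Whether standardization should precede
centering is not determined by the method description; we center first,
which makes the result invariant to per-feature affine offsets.
Zero-variance features are left centered rather than divided, with a
warning. `window_average()` means the bins whose onsets fall in
`[start, start + length)` relative to the go cue.

## Decoding

`nested_cv_gnb()` is a Gaussian naive Bayes classifier over
window-averaged vectors with nested cross-validation of the window start:
stratified outer folds; per outer fold an inner stratified k-fold accuracy
for each candidate start on training data only; best start (ties to the
earliest, making selection deterministic) applied to the held-out fold.
Test-fold success indicators are pooled and given an exact Clopper-Pearson
interval from Beta quantiles; decoding is significant when the lower bound
clears 1/`n_classes`. Per-class variances get a `1e-9` floor so degenerate
features cannot produce infinite likelihoods. Fold assignment is seeded;
candidate starts are bin-aligned.

Because the exact interval is conservative, the false-significance rate of
"CI excludes chance" on tuning-free sessions sits below the nominal 5%
(the acceptance suite measures it over 200 simulated sessions at 7 words ×
30 trials).

## Neural geometry

The plug-in distance $\lVert \bar x_a - \bar x_b \rVert$ is biased upward
by observation noise; the plug-in correlation is biased toward zero for
the same reason (noise inflates the magnitude terms in its denominator).
Both estimators here replace noisy squared magnitudes with cross-split
inner products: trials of each condition are split into disjoint random
halves, and

$$\widehat{d^2} = \bigl\langle \bar x_a^{(1)} - \bar x_b^{(1)},\;
  \bar x_a^{(2)} - \bar x_b^{(2)} \bigr\rangle$$

is unbiased for $\lVert \mu_a - \mu_b \rVert^2$ because the two halves
carry independent noise. We average over 100 random half-splits by default
(the number of splits is an exposed parameter; more splits only reduce
Monte-Carlo variance) and return the signed square root, keeping negative
estimates so null distributions stay centered at zero rather than folding
into a positive bias. Note $E[\sqrt{X}] \le \sqrt{E[X]}$: the root
estimate itself is slightly conservative at low trial counts, which is
visible in the acceptance measurements (≈2% low at 100 trials/condition).

The cross-validated correlation divides the cross-condition inner product
by the square roots of each condition's cross-split self inner product.
When modulation is weak the denominator is an unbiased estimate of a small
quantity, so the ratio can exceed 1; such values are evidence that the
true correlation is near 1, and nonpositive magnitude estimates return
`NaN` with a warning instead of a fabricated value. Word-pair correlations
require subtracting each behavior's grand mean first
(`subtract_word_mean()`); whole-behavior correlations concatenate each
trial index's per-word vectors (`behavior_vectors()`).

`normalized_distances()` averages the 21 word-pair distances within each
behavior and divides by the attempted-speech average, recovering each
behavior's modulation scale; `pca_word_rings()` projects condition means
onto top principal components fit on a configurable condition subset
(attempted words only, or all conditions of an interleaved session).

## Motor intent

Centroids per behavior are computed as the average of per-word trial
means, so unequal trial counts across words do not reweight the centroid.
The motor-intent direction is the unit difference of centroids; removal
subtracts the projection. Inside cross-validated decoding the direction is
refit on each training fold and applied to both sides, so removal never
sees test data — the method description leaves this open, and refitting is
the leakage-safe choice. Removal collapses behavior accuracy to chance
only when the across-behavior offset is close to rank-1 in the analyzed
feature space *and* observation noise is behavior-independent; with count
noise, variance differences between behaviors retain some behavior
information after mean removal, which mirrors the observation that
14-class decoding stays above chance after projection in real recordings.

## Sequences, text metrics, controls

Position-wise sequence decoding fits one binary LDA per pair of sequences
differing at exactly one position (context held fixed), 5-fold
cross-validated, with the pooled covariance shrunk toward its diagonal
(default 0.1) for small-sample stability. Per-decoder outcome vectors are
bootstrapped (default 10,000 resamples), pooled within position weighted
by trial count, and significance read from the 2.5th percentile against
chance 0.5; verbal-versus-visual strategy effects subtract paired decoder
accuracies within bootstrap iterations. Cross-task transfer fits on all
trials of one task and evaluates on the matching pairs of another.

Aggregate word error rate is total word-level edit errors over total
reference words (greater than 100% is possible and meaningful), with
bootstrap CIs over sentence pairs and a permutation chance level defined
as the 2.5th percentile of aggregate WER over reshuffled
reference-decoded pairings (default 10,000 shuffles; a 100-shuffle variant
is a parameter, matching the cheaper setting sometimes used for online
summaries). All pairwise sentence distances are cached once, so shuffles
are index operations.

DTW uses the symmetric2 step pattern (diagonal moves cost twice the local
Euclidean distance) under a slanted band of half-width 100 ms around the
uniform-rescaling line, which bounds how far alignment can deviate from a
constant rate change; correlations are computed per phoneme dimension on
the warped pair (silence excluded, zero-variance dimensions skipped with a
warning) and averaged.

The counting-slope analysis pools `(position, decoded number)` points
across trials — positions indexed from 0; the slope is origin-invariant —
and its null stitches together `stitch_k = 3` control sequences per
pseudo-trial to match counting-trial durations, re-estimating the slope
over 1,000 resamples. A single control set leaves a small conditional
offset in the null mean (the resamples reuse the same finite corpus); the
observed-percentile calibration, which draws fresh controls, is uniform
under the null. The articulatory-length control regresses the 21 pairwise
neural distances on absolute duration differences with an intercept and a
two-tailed slope test at $\alpha = 0.05$.

## Orchestration, sizes, limitations

`run_pipeline()` executes toggled stages from a seed-explicit config
(YAML/JSON round-trip), writes one CSV per stage plus `summary.json`, and
aborts naming the failing stage while retaining earlier outputs. Sessions
serialize to a plain-text bundle (`features.csv` + `meta.json`) readable
without special tooling.

Default problem sizes throughout the tests and the acceptance script —
30–40 trials per condition, 24–64 features, 50–200 simulated sessions for
calibration rates, 1,000-resample nulls — were chosen so the full suite
runs in minutes on a laptop while keeping Monte-Carlo error well inside
each tolerance; they are not estimates of any recording's parameters.

What passing tests on synthetic sessions do **not** show: robustness to
non-Poisson overdispersion, within-block nonstationarity, electrode
correlation structure, behavioral timing variability beyond the uniform
stretch used for logit pairs, or any property of real decoder (RNN)
outputs — counting and WER analyses consume decoded sequences as inputs by
design. The generator's temporal kernel and noise families are idealized;
conclusions about real recordings require real recordings.
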