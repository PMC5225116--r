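---
title: "Estimating mental workload from EEG band power with GPR-ARD: models and methods"
author: "gprload"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mental workload from EEG band power with GPR-ARD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements,
the defaults it pins, and the choices made where the design was
genuinely open. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

# The task model

An N-back block presents 100 comparison trials of one stimulus mode
(Auditory, Numeric or Spatial) at one level N in 1..3. Eight stimuli are
available; each trial draws one uniformly, and then — independently, with
probability 1/8, for trials deeper than N into the block — the draw is
overwritten with the stimulus N positions back ("forced" match). Because
the overwrite uses the *final* value of the earlier trial, overwrites
chain; `generateBlock()` resolves the chain exactly and computes
`isMatch` from the final sequence. The long-run match probability for
eligible trials is therefore 1/8 + 7/8 · 1/8 = 1 − (7/8)² = 23.44%,
which is also the ceiling for the accuracy measure TP/(TP+FP+FN) under a
respond-always policy. Note one finite-block effect: the first N trials
of a block can never match, so at 100 trials per block the respond-all
accuracy sits about half a percentage point below the asymptotic
ceiling. Whether a forced overwrite may land on a trial whose random
draw already matched is not observable from the match rate alone; the
implementation lets it (draw first, then an independent overwrite),
which reproduces the 76.56% / 23.44% split exactly.

Sessions hold one block per (mode, level) cell — 9 blocks, 900 trials —
with levels ascending within each mode and mode order counterbalanced
across participants by a Latin square indexed by participant number.
A configurable `blocksPerCell` permits larger designs.

Simulated responses (hit and false-alarm probabilities per level) and
1–7 subjective ratings (per-level discretized normals centered at 2, 4,
6) are plumbing with plausible defaults; they carry no ground-truth
status and exist so that behavioral quantities (accuracy, rating
monotonicity) are computable.

# The synthetic EEG generator

No human recordings are available, so the package generates epochs whose
relationship to task level is known exactly. Each epoch (3 s at 250 Hz,
one row per channel) is a sum of six band-limited oscillations — one per
frequency band, at the spectral-bin center nearest the band midpoint,
with a fresh random phase per trial — plus Gaussian background noise
spectrally confined to 1–45 Hz.

The controlled quantity is the **log band power**. For feature
(channel, band) its per-trial value is drawn as

&nbsp;&nbsp;g ~ Normal( baseline + slope · (N − 2), noiseSd ),

and the oscillation amplitude is set to `sqrt(exp(g) / c_band)`, where
`c_band` is the measured band power of a unit-amplitude carrier through
the package's own Welch stage. This calibration makes the spectral stage
a genuine, testable transformation: extracted log band powers reproduce
`g` up to estimation error, and regression of a feature on N recovers
`slope` (a property test in the suite).

Two deliberate choices:

* **Log-domain control.** Controlling log power (not raw power) matches
  the pipeline's log transform and makes effect sizes additive.
* **Centering at the middle level.** The level effect enters as
  slope · (N − 2), so `baseline` is the feature's typical value. This
  matters for mode-specific signatures: a feature that indexes load only
  in one task variant rests at its typical value — not at a "level-0"
  extrapolation — during the other variants, which is both the realistic
  reading and what produces the observed transfer structure (matched
  variants decode, mismatched variants do no better than the mean
  predictor).

Defaults: noiseSd 0.5 log units (trial-to-trial variability of the same
order as the level effect across the 1→3 range), slope 0.25 per level
step on beta and gamma power at lateral temporal and occipital sites
(T7, T8, P7, P8, O1, Oz, O2), per-band baselines falling with frequency
(3.0 down to 1.0 log units), background noise SD 1.0 signal units
(≈ 1% of band power). These emulate the qualitative structure the
analysis is meant to detect — higher-frequency features at lateral and
occipital sites carrying load information — and nothing more. The
generator has no 1/f background, no volume conduction, no artifacts
(blinks, EMG), and no nonstationarity, so passing tests demonstrate the
pipeline's correctness and its behavior under a known signal model, not
performance on real EEG.

# Feature extraction

Welch PSD per channel: Hamming windows of 500 samples (2 s), 250-sample
overlap, 512-point FFT; only full segments are used, so a 750-sample
epoch contributes exactly two segments (offsets 0 and 250). Scaling is
density normalization, 1/(fs · Σw²), one-sided with interior bins
doubled (DC and Nyquist not) — conventions chosen to match the common
MATLAB/scipy symmetric-Hamming convention, frozen against an independent
implementation in the tests. Any fixed convention cancels in the later
z-scoring, but one must be pinned for the stage to be testable.

Band power is the *mean* of the PSD bins whose center frequency lies in
the closed band interval ("averaged into bands" is taken literally, as
opposed to integrated power). The printed band edges are gapped (e.g.
3–4 Hz); bins falling between bands belong to none. Features are the
natural log of band power, ordered channel-major (six bands within each
channel), and z-scored per feature with mean and SD computed on training
rows only — test rows are placed on the training scale, as required both
for leakage-free evaluation and for online use where test statistics are
unknowable. Zero-SD training features are flagged and mapped to 0.

# The GP regressor

Exact GPR with the squared-exponential ARD kernel, constant zero mean
(the targets are modeled after z-scored inputs; the zero mean is a
modeling choice, not a data transform on y) and Gaussian likelihood. The
training objective is the standard zero-mean negative log marginal
likelihood ½ yᵀ(K+σ_n²I)⁻¹y + ½ log|K+σ_n²I| + (n/2) log 2π with
analytic gradients with respect to the log hyperparameters. All
hyperparameters are represented and optimized on the log scale.

Numerical policy:

* **Factorization.** Cholesky of K + σ_n²I with escalating jitter on
  failure: starting at 1e-10 × mean diagonal, ×10 per retry, at most 3
  retries, then a hard error (never silent). Prediction solves
  triangular systems; no explicit inverse is formed on the prediction
  path.
* **Optimizer.** L-BFGS-B (deterministic, quasi-Newton) on the log
  hyperparameters, capped at 100 iterations; each iteration spends one
  function-plus-gradient evaluation plus any line-search evaluations, so
  the cap is the package's concrete reading of a "100 function
  evaluations" budget, documented rather than guessed. Convergence uses
  `optim`'s default `factr`/`pgtol`. The returned model never has a
  higher objective than its initialization (falls back to the initial
  hyperparameters if the optimizer misbehaves).
* **Initialization.** ℓ_d = 10 for every feature, σ_f² = 1, σ_n² = 1 —
  sensible on z-scored inputs (features have unit scale; targets have
  variance below 1).
* **Variances.** Latent posterior variances that fall below zero by
  round-off are clamped to 0 with a message. Both the latent variance
  and the observation variance (latent + σ_n²) are stored; ±2σ intervals
  are meant to use the observation variance.

**Feature-subset prediction.** `predictWithFeatureSubset()` evaluates
the trained kernel over the retained dimensions only, with the training
inputs restricted to the same columns and the trained length scales
reused. Hyperparameters are *not* refit by default: the regime of
interest is a model calibrated on a full laboratory montage and deployed
on a reduced one, and ARD's robustness to deleted features is exactly
what the sweep and montage experiments measure. `refit = TRUE` exposes
the alternative.

# Baselines and interpretation

The MLR baseline is ordinary least squares with one weight per feature
plus an intercept (minimum-norm solution with a warning when the design
is rank deficient). Haufe activation patterns are A = Σ_x W / var(ŝ);
the latent factor ŝ defaults to the model's fitted predictions, with the
labels themselves selectable — the two readings coincide up to scale for
a least-squares fit, and neither is asserted as canonical. Note the
covariance-transformation law: scaling a feature by c scales its weight
by 1/c and its *activation* by c (patterns live in measurement units).
Per-feature one-way ANOVA F uses the classical between/within
mean-square ratio, vectorized across features and checked against
`stats::aov`; when selection is based on ANOVA it is computed on
training folds only.

# Cross-validation and metrics

Each block is cut into k = 5 contiguous partitions (earlier partitions
absorb the remainder when the block length is not divisible by k); fold
i tests partition i of every block. Test trials within 5 trials
(within-block index distance) of any training trial are removed from the
test set only, keeping training at 80% everywhere; trials in different
blocks are never buffered against each other, since blocks are separated
by breaks. On clean 100-trial blocks this retains 15 test trials for
edge partitions and 10 for interior ones. A leakage invariant
(min distance > buffer) is asserted by recomputation in the tests.

sMSE divides the mean squared error by the *population* variance
(divide by n) of the true test values: under that convention — and only
under a consistent one — the constant mean predictor scores exactly 1.
Pearson r is the standard product-moment correlation; discretized
classification rounds each prediction to the nearest training-set label
with ties to the smaller label. Pooled metrics concatenate all folds'
(truth, prediction) pairs; per-fold metrics are reported alongside, and
on balanced folds the two sMSE readings agree closely. Subjective-label
runs assign the block's single rating to every trial of the block.

The cross-variant matrix trains, per fold, on one variant's training
trials and tests on another variant's retained test trials, pooling over
folds into a 3 × 3 sMSE table (rows = training variant). The feature
sweep ranks features per fold by that fold's trained length scales
(training data only) and re-evaluates the fold's test set at each
retained percentage without refitting; with the package's planted-signal
defaults the curve plateaus once roughly the top quarter of features is
retained, and the 100% point equals the full model by construction.

# Problem sizes used by the tests

The test suite and acceptance checks run at sizes chosen to exercise the
full study structure while staying desk-scale: stimulus-model arithmetic
uses ≥ 10⁶ simulated trials; GP oracle checks use n ≤ 50 with explicit
dense inverses; hyperparameter recovery draws n = 300 with 5 features
from the GP prior (documented tolerance: 0.75 on the log scale, against
observed recovery errors well inside that); relevance-ranking stability
uses 20 independent 150 × 10 problems; and the end-to-end pipeline
properties run full 900-trial sessions on an 8-channel montage
(48 features) — the montage, not the session, is the scaled dimension,
because the session's 9-block structure is what the CV, buffer and
transfer analyses depend on.

# Known limitations

* The synthesizer's additive narrowband model is an emulation target,
  not a generative account of EEG; results on it say nothing about
  human-data performance.
* Exact GPR is O(n³) in training-set size; the package is sized for
  single-session analyses (n in the hundreds), not streaming use.
* Only the squared-exponential ARD kernel and Gaussian likelihood are
  provided; covariances with linear terms (which would help
  extrapolation beyond the training range of N) are out of scope.
* The accuracy measure's denominator can be zero in degenerate blocks
  (no matches, no responses); it is returned as NA, not 0.
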