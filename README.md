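# gprload

Continuous mental workload estimation from EEG band power with Gaussian
process regression and automatic relevance determination (ARD).

## The problem

Passive brain-computer interfaces try to track a user's cognitive state —
here, working-memory load — from ongoing EEG. In the N-back paradigm the
imposed load is the level N (1, 2 or 3): the participant must respond
whenever the current stimulus matches the one presented N positions
earlier. Although the task visits load at discrete levels, the underlying
mental state is better treated as continuous, which calls for regression
rather than classification, and for an error measure on a continuous
scale.

`gprload` implements that analysis end to end for *synthetic* data with a
known ground truth (no human recordings ship with the package):

1. **N-back simulator** — sessions of 9 blocks (3 stimulus modes ×
   levels 1–3) of 100 comparison trials. Each trial's stimulus is drawn
   uniformly from 8 alternatives and then, independently with probability
   1/8, overwritten with the stimulus N back, so the long-run match
   probability is 1/8 + 7/8 · 1/8 = 23.44%. Responses, the
   TP/(TP+FP+FN) accuracy measure, and 1–7 subjective workload ratings
   are simulated on top.
2. **EEG synthesizer** — per-trial 32-channel, 3-s epochs at 250 Hz whose
   *log band power* carries a planted, per-(channel, band) linear effect
   of N, so every later stage can be tested against a known truth.
3. **Feature extraction** — Welch spectra (Hamming windows of 500
   samples, 250-sample overlap, 512-point FFT) averaged into six bands
   (delta 1–3, theta 4–7, low alpha 8–10, high alpha 11–12, beta 13–25,
   gamma 26–40 Hz), log-transformed, and z-scored with training-set
   statistics only. A 32-channel montage yields 6 × 32 = 192 features.
4. **GPR core** — exact Gaussian process regression with the
   squared-exponential ARD covariance

   k(x_p, x_q) = σ_f² · exp( −½ (x_p − x_q)ᵀ diag(ℓ)⁻² (x_p − x_q) ),

   zero mean and Gaussian likelihood. Hyperparameters (one length scale
   ℓ_d per feature, signal variance σ_f², noise variance σ_n²) start at
   ℓ = 10, σ_f² = 1, σ_n² = 1 and are optimized by minimizing the
   negative log marginal likelihood with analytic gradients under a
   100-evaluation budget. Prediction uses the standard posterior mean
   K(X*,X)[K(X,X)+σ_n²I]⁻¹y and variance via a cached Cholesky
   factorization. Short trained length scales mark the features the
   model relies on; a model trained on all features can be applied to
   any feature subset without refitting.
5. **Baselines and interpretation** — multiple linear regression, Haufe
   activation patterns A = Σ_x W / var(ŝ), and per-feature one-way
   ANOVA F for level.
6. **Evaluation** — five-fold cross-validation blocked within each of
   the 9 blocks, with a 5-trial buffer removing test trials adjacent to
   training trials (from the test set only); standardized MSE
   (MSE / variance of truth, so the mean predictor scores exactly 1),
   Pearson r, discretized classification accuracy; feature-percentage
   sweeps, reduced electrode montages, and a 3 × 3 cross-task-variant
   transfer matrix.

## Worked example

```r
library(gprload)

session  <- generateSession("P01", seed = 1)
chans    <- c("T7", "T8", "P7", "P8", "O1", "O2")
profile  <- makeParticipantProfile(chans,
              relevanceSpec = defaultRelevanceSpec(chans), seed = 2)
epochs   <- synthesizeSessionEpochs(session, profile, seed = 3)
features <- extractFeatures(epochs)
plan     <- makeCvPlan(trialLabels(features))
plan
#> CVPlan: 5 folds, buffer 5; retained test trials per fold: 135, 90, 90, 90, 135

runCv(features, plan, method = "gpr")
#> CvResult (gpr, label = level): pooled sMSE 0.312, r 0.830, acc 0.728 over 540 test trials
runCv(features, plan, method = "mlr", keepModels = FALSE)
#> CvResult (mlr, label = level): pooled sMSE 0.336, r 0.816, acc 0.700 over 540 test trials
```

The session holds 900 trials; each fold's test partitions lose the
trials within five of the training set (20 → 15 at a block edge,
20 → 10 in the interior), leaving 540 scored trials. sMSE of 0.31 means
the GP's squared error is 31% of the naive always-predict-the-mean
error; the linear baseline trails it. The trained length scales recover
the planted relevance (beta/gamma power at lateral and occipital sites):

```r
cv <- runCv(features, plan, method = "gpr")
ranking <- lengthScales(cv@models[[1]]$model)
head(ranking[order(ranking$rank), ], 4)
#>     feature lengthScale rank
#> 24 P8.gamma    5.144003    1
#> 30 O1.gamma    7.209278    2
#> 23  P8.beta    7.348484    3
#> 29  O1.beta    9.515932    4
```

`featureSweep()`, `montageSubsetEval()` and `crossVariantEval()` build
on the same fitted folds; `runPipeline(pipelineConfig(...), outDir)`
runs every stage end to end and writes CSV/JSON artifacts stamped with
the configuration hash and seed.

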