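#' @import methods
NULL

#' NBackBlock: one block of N-back trials
#'
#' A single block of comparison trials sharing one stimulus mode and one
#' task level N. Trials are stored as a data.frame with columns `index`
#' (1-based position), `stimulus` (integer code in 1..8), `isMatch` (current
#' stimulus equals the stimulus N back), `forced` (the match was imposed by
#' the generator rather than arising from the uniform draw) and `responded`
#' (logical; NA until responses are simulated).
#'
#' @slot mode Character; one of "Auditory", "Numeric", "Spatial".
#' @slot level Integer N in 1..3.
#' @slot trials data.frame of per-trial records.
#' @slot rating Integer subjective workload rating in 1..7, or NA.
#' @exportClass NBackBlock
setClass("NBackBlock",
  representation(mode = "character", level = "integer",
                 trials = "data.frame", rating = "integer"),
  prototype(rating = NA_integer_))

setValidity("NBackBlock", function(object) {
  msg <- character()
  if (!object@mode %in% TASK_MODES) msg <- c(msg, "unknown mode")
  if (!object@level %in% 1:3) msg <- c(msg, "level must be in 1..3")
  req <- c("index", "stimulus", "isMatch", "forced", "responded")
  if (!all(req %in% names(object@trials))) {
    msg <- c(msg, paste("trials must have columns:", paste(req, collapse = ", ")))
  } else {
    tr <- object@trials
    if (any(!tr$stimulus %in% seq_len(N_STIMULI)))
      msg <- c(msg, "stimulus codes must be in 1..8")
    if (any(tr$isMatch[tr$index <= object@level]))
      msg <- c(msg, "isMatch must be FALSE for trials with index <= N")
    if (any(tr$forced & !tr$isMatch))
      msg <- c(msg, "forced implies isMatch")
  }
  if (!is.na(object@rating) && !object@rating %in% 1:7)
    msg <- c(msg, "rating must be in 1..7 or NA")
  if (length(msg)) msg else TRUE
})

#' NBackSession: an ordered set of N-back blocks for one participant
#'
#' @slot participant Character label.
#' @slot blocks List of [NBackBlock-class] objects; levels ascend within
#'   each mode and modes follow `modeOrder`.
#' @slot modeOrder Character permutation of the three stimulus modes.
#' @exportClass NBackSession
setClass("NBackSession",
  representation(participant = "character", blocks = "list",
                 modeOrder = "character"))

setValidity("NBackSession", function(object) {
  msg <- character()
  if (!all(vapply(object@blocks, is, logical(1), "NBackBlock")))
    msg <- c(msg, "blocks must all be NBackBlock objects")
  if (!setequal(object@modeOrder, TASK_MODES) ||
      length(object@modeOrder) != 3L)
    msg <- c(msg, "modeOrder must be a permutation of the three modes")
  modes <- vapply(object@blocks, function(b) b@mode, character(1))
  levels <- vapply(object@blocks, function(b) b@level, integer(1))
  for (m in unique(modes)) {
    lv <- levels[modes == m]
    percell <- table(lv)
    if (!all(sort(unique(lv)) == seq_along(unique(lv))) ||
        !all(diff(lv) >= 0))
      msg <- c(msg, sprintf("levels must ascend within mode %s", m))
    if (length(unique(percell)) > 1L)
      msg <- c(msg, sprintf("unbalanced blocks per level in mode %s", m))
  }
  if (length(msg)) msg else TRUE
})

#' ParticipantProfile: ground truth for the synthetic-EEG generator
#'
#' Encodes, per (channel, band) feature, the mean log band power as an
#' affine function of task level N: `baseline + slope * (N - 2)` (the
#' level effect is centered at the middle level, so `baseline` is the
#' feature's typical value), with trial-to-trial standard deviation
#' `noiseSd` on the log scale. Slopes may
#' differ by stimulus mode (third array dimension), which is how
#' mode-specific level signatures are planted for transfer experiments.
#' The profile is retained alongside synthesized epochs so that recovery
#' tests can compare extracted features against the generating truth.
#'
#' @slot channelNames Character vector.
#' @slot bands Band-definition data.frame (see [defaultBands()]).
#' @slot baseline Numeric matrix channels x bands; level-independent mean
#'   log band power.
#' @slot slopes Numeric array channels x bands x modes; change in mean log
#'   band power per unit of N.
#' @slot noiseSd Numeric matrix channels x bands; per-trial SD of log band
#'   power (>= 0).
#' @slot broadbandSd Numeric scalar; SD of the band-limited (1-45 Hz)
#'   background noise added to every channel, in signal units.
#' @exportClass ParticipantProfile
setClass("ParticipantProfile",
  representation(channelNames = "character", bands = "data.frame",
                 baseline = "matrix", slopes = "array",
                 noiseSd = "matrix", broadbandSd = "numeric"))

setValidity("ParticipantProfile", function(object) {
  msg <- character()
  nc <- length(object@channelNames)
  nb <- nrow(object@bands)
  if (!all(dim(object@baseline) == c(nc, nb)))
    msg <- c(msg, "baseline must be channels x bands")
  if (!all(dim(object@slopes) == c(nc, nb, 3L)))
    msg <- c(msg, "slopes must be channels x bands x 3 modes")
  if (!all(dim(object@noiseSd) == c(nc, nb)))
    msg <- c(msg, "noiseSd must be channels x bands")
  if (any(object@noiseSd < 0)) msg <- c(msg, "noiseSd must be >= 0")
  if (object@broadbandSd < 0) msg <- c(msg, "broadbandSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' EpochedSession: per-trial multi-channel EEG epochs plus labels
#'
#' @slot epochs Numeric array trials x channels x samples.
#' @slot channelNames Character vector, length = dim 2.
#' @slot sampleRate Sampling rate in Hz (default 250).
#' @slot labels data.frame of per-trial labels aligned with dim 1
#'   (participant, mode, level, block, trial, isMatch, responded, rating).
#' @slot profile The generating [ParticipantProfile-class], or NULL for
#'   user-supplied data.
#' @exportClass EpochedSession
setClass("EpochedSession",
  representation(epochs = "array", channelNames = "character",
                 sampleRate = "numeric", labels = "data.frame",
                 profile = "ANY"))

setValidity("EpochedSession", function(object) {
  msg <- character()
  d <- dim(object@epochs)
  if (length(d) != 3L) msg <- c(msg, "epochs must be a 3-d array")
  else {
    if (d[2] != length(object@channelNames))
      msg <- c(msg, "channel dimension must match channelNames")
    if (d[1] != nrow(object@labels))
      msg <- c(msg, "epoch count must equal label row count")
  }
  if (length(msg)) msg else TRUE
})

#' WorkloadFeatures: trials-by-feature log band-power container
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding
#' one assay `"logpower"` with one row per (channel, band) feature and one
#' column per trial. `rowData` carries `channel` and `band`; `colData`
#' carries the per-trial labels (mode, level, block, trial, rating, ...).
#'
#' @exportClass WorkloadFeatures
#' @import SummarizedExperiment
setClass("WorkloadFeatures", contains = "SummarizedExperiment")

setValidity("WorkloadFeatures", function(object) {
  msg <- character()
  if (!"logpower" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "must carry an assay named 'logpower'")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("channel", "band") %in% names(rd)))
    msg <- c(msg, "rowData must have 'channel' and 'band'")
  if (length(msg)) msg else TRUE
})

#' NormalizerStats: train-set z-scoring statistics
#'
#' Per-feature mean and standard deviation computed on training rows only;
#' applied unchanged to both training and test rows. Features constant on
#' the training set (zero SD) are flagged and mapped to 0 everywhere.
#'
#' @slot mean Numeric vector of per-feature training means.
#' @slot sd Numeric vector of per-feature training SDs.
#' @slot constant Logical vector marking zero-SD features.
#' @exportClass NormalizerStats
setClass("NormalizerStats",
  representation(mean = "numeric", sd = "numeric", constant = "logical"))

#' GPModel: trained exact Gaussian process regressor
#'
#' Retains the training inputs and targets together with the optimized
#' hyperparameters of the squared-exponential ARD covariance (one length
#' scale per feature, signal variance, noise variance, all kept on the log
#' scale internally) and a cached Cholesky factorization of
#' K(X,X) + sigma_n^2 I.
#'
#' @slot X Numeric matrix of training inputs, trials x features.
#' @slot y Numeric vector of training targets.
#' @slot logTheta Numeric vector `c(log lengthscales, log signalVar,
#'   log noiseVar)`.
#' @slot featureNames Character vector naming the columns of X.
#' @slot U Upper-triangular Cholesky factor of K + sigma_n^2 I (+ jitter).
#' @slot alpha Cached solve of (K + sigma_n^2 I) against y.
#' @slot jitter Jitter added to the diagonal during factorization (0 if
#'   none was needed).
#' @slot nlmlPath Numeric vector of objective values recorded during
#'   training (first entry = value at initialization).
#' @slot nlml Final negative log marginal likelihood.
#' @exportClass GPModel
setClass("GPModel",
  representation(X = "matrix", y = "numeric", logTheta = "numeric",
                 featureNames = "character", U = "matrix",
                 alpha = "numeric", jitter = "numeric",
                 nlmlPath = "numeric", nlml = "numeric"))

setValidity("GPModel", function(object) {
  msg <- character()
  d <- ncol(object@X)
  if (length(object@logTheta) != d + 2L)
    msg <- c(msg, "logTheta must have one length scale per feature plus signal and noise variances")
  if (nrow(object@X) != length(object@y))
    msg <- c(msg, "rows of X must align with y")
  if (length(msg)) msg else TRUE
})

#' MLRModel: multiple linear regression baseline
#'
#' One linear term per feature plus a constant term, fit by least squares
#' (minimum-norm solution when the design is rank deficient).
#'
#' @slot weights Numeric vector, one per feature.
#' @slot intercept Numeric scalar.
#' @slot featureNames Character vector.
#' @exportClass MLRModel
setClass("MLRModel",
  representation(weights = "numeric", intercept = "numeric",
                 featureNames = "character"))

#' CVPlan: blocked cross-validation plan with leakage buffer
#'
#' Each block of trials is cut into `k` contiguous partitions; fold i holds
#' out partition i of every block as the test set and trains on the rest.
#' Test trials lying within `buffer` trials (within-block index distance)
#' of any training trial are dropped from the test set only, keeping the
#' training set at a constant k-1 partitions per block.
#'
#' @slot k Integer fold count.
#' @slot buffer Integer trial-distance threshold.
#' @slot folds List of `k` lists with integer elements `train` and `test`
#'   (global trial indices; `test` already buffered).
#' @slot nTrials Total trial count the plan indexes into.
#' @exportClass CVPlan
setClass("CVPlan",
  representation(k = "integer", buffer = "integer", folds = "list",
                 nTrials = "integer"))

setValidity("CVPlan", function(object) {
  msg <- character()
  for (f in object@folds) {
    if (length(intersect(f$train, f$test)))
      msg <- c(msg, "train and test must be disjoint within a fold")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' PredictionSet: per-trial posterior predictions with truth
#'
#' @slot truth Numeric vector of true labels (NA when unknown).
#' @slot mean Posterior mean per test trial.
#' @slot varLatent Posterior variance of the latent function.
#' @slot varObs Posterior variance of observations (latent + noise
#'   variance); the plotted +/- 2 sigma band uses this.
#' @slot fold Integer fold id per trial (NA outside cross-validation).
#' @exportClass PredictionSet
setClass("PredictionSet",
  representation(truth = "numeric", mean = "numeric",
                 varLatent = "numeric", varObs = "numeric",
                 fold = "integer"))

setValidity("PredictionSet", function(object) {
  n <- length(object@mean)
  msg <- character()
  if (length(object@truth) != n || length(object@varLatent) != n ||
      length(object@varObs) != n || length(object@fold) != n)
    msg <- c(msg, "all slots must have equal length")
  if (any(object@varLatent < 0, na.rm = TRUE) ||
      any(object@varObs < 0, na.rm = TRUE))
    msg <- c(msg, "variances must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' CvResult: fitted models, predictions and metrics from one CV run
#'
#' @slot predictions data.frame with one row per retained test trial:
#'   fold, trial index, labels, truth, prediction, variances.
#' @slot pooled Named list of pooled-over-folds metrics (smse, r,
#'   classification accuracy).
#' @slot perFold data.frame of the same metrics computed within fold.
#' @slot models List (one per fold) with the fitted model, normalizer and
#'   the normalized test inputs/targets, for subset re-evaluation.
#' @slot method "gpr" or "mlr".
#' @slot labelKind "level" or "subjective".
#' @slot plan The [CVPlan-class] used.
#' @exportClass CvResult
setClass("CvResult",
  representation(predictions = "data.frame", pooled = "list",
                 perFold = "data.frame", models = "list",
                 method = "character", labelKind = "character",
                 plan = "CVPlan"))

## ---- show methods -------------------------------------------------------

setMethod("show", "NBackBlock", function(object) {
  cat(sprintf("NBackBlock: %s %d-back, %d trials, %d matches (%d forced), rating %s\n",
              object@mode, object@level, nrow(object@trials),
              sum(object@trials$isMatch), sum(object@trials$forced),
              ifelse(is.na(object@rating), "unset", object@rating)))
})

setMethod("show", "NBackSession", function(object) {
  nt <- sum(vapply(object@blocks, function(b) nrow(b@trials), integer(1)))
  cat(sprintf("NBackSession '%s': %d blocks, %d trials, mode order %s\n",
              object@participant, length(object@blocks), nt,
              paste(object@modeOrder, collapse = " > ")))
})

setMethod("show", "ParticipantProfile", function(object) {
  cat(sprintf("ParticipantProfile: %d channels x %d bands, %d relevant features\n",
              length(object@channelNames), nrow(object@bands),
              sum(apply(object@slopes != 0, c(1, 2), any))))
})

setMethod("show", "EpochedSession", function(object) {
  d <- dim(object@epochs)
  cat(sprintf("EpochedSession: %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], object@sampleRate))
})

setMethod("show", "GPModel", function(object) {
  d <- ncol(object@X)
  cat(sprintf("GPModel: n = %d, %d features; NLML %.3f (init %.3f); sf2 = %.3g, sn2 = %.3g\n",
              nrow(object@X), d, object@nlml, object@nlmlPath[1],
              exp(object@logTheta[d + 1L]), exp(object@logTheta[d + 2L])))
})

setMethod("show", "CVPlan", function(object) {
  nt <- vapply(object@folds, function(f) length(f$test), integer(1))
  cat(sprintf("CVPlan: %d folds, buffer %d; retained test trials per fold: %s\n",
              object@k, object@buffer, paste(nt, collapse = ", ")))
})

setMethod("show", "PredictionSet", function(object) {
  cat(sprintf("PredictionSet: %d predictions\n", length(object@mean)))
})

setMethod("show", "CvResult", function(object) {
  cat(sprintf("CvResult (%s, label = %s): pooled sMSE %.3f, r %.3f, acc %.3f over %d test trials\n",
              object@method, object@labelKind, object@pooled$smse,
              object@pooled$r, object@pooled$accuracy,
              nrow(object@predictions)))
})
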