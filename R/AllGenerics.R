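#' Flatten a session into one data.frame of trials
#'
#' @param x An [NBackSession-class] or [NBackBlock-class].
#' @return data.frame with columns participant (sessions only), mode,
#'   level, block, trial, stimulus, isMatch, forced, responded, rating.
#' @export
setGeneric("sessionTrials", function(x) standardGeneric("sessionTrials"))

#' Per-feature ARD relevance from a trained GP model
#'
#' Shorter length scales mean the model is more sensitive to a feature.
#' Ranks ascend with length scale (rank 1 = most relevant); ties are broken
#' by feature index.
#'
#' @param model A trained [GPModel-class].
#' @return data.frame with columns `feature`, `lengthScale`, `rank`.
#' @export
setGeneric("lengthScales", function(model) standardGeneric("lengthScales"))

#' Retained training hyperparameters of a GP model
#'
#' @param model A trained [GPModel-class].
#' @return Named list with `lengthScales`, `signalVar`, `noiseVar` on the
#'   natural scale.
#' @export
setGeneric("hyperparams", function(model) standardGeneric("hyperparams"))

#' Extract per-trial labels from a feature container
#'
#' @param x A [WorkloadFeatures-class] or [EpochedSession-class].
#' @return data.frame of per-trial labels.
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))

#' Trials-by-features numeric matrix from a feature container
#'
#' @param x A [WorkloadFeatures-class].
#' @return Numeric matrix, one row per trial, one column per (channel,
#'   band) feature.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
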