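## Blocked cross-validation with a temporal leakage buffer, metrics, and
## the feature-subset / montage / cross-variant experiments.

#' Build a blocked cross-validation plan with leakage buffer
#'
#' Each block's trials are cut into `k` contiguous, near-equal partitions
#' (earlier partitions absorb any remainder). Fold i tests partition i of
#' every block and trains on the other k-1 partitions. Test trials whose
#' within-block index lies within `buffer` trials of any training trial of
#' the same block are removed from the test set only, so the training set
#' stays at k-1 partitions per block. Trials in different blocks are never
#' buffered against each other (blocks are separated by breaks).
#'
#' @param labels data.frame with one row per trial carrying columns
#'   `block` and `trial` (within-block 1-based index), in the row order of
#'   the feature matrix the plan will index.
#' @param k Fold count (default 5).
#' @param buffer Trial-distance threshold (default 5).
#' @return A [CVPlan-class].
#' @export
#' @examples
#' lab <- data.frame(block = 1, trial = 1:100)
#' makeCvPlan(lab)
makeCvPlan <- function(labels, k = 5L, buffer = 5L) {
  stopifnot(all(c("block", "trial") %in% names(labels)))
  k <- as.integer(k); buffer <- as.integer(buffer)
  stopifnot(k >= 2L, buffer >= 0L)
  n <- nrow(labels)
  folds <- replicate(k, list(train = integer(0), test = integer(0)),
                     simplify = FALSE)
  for (b in unique(labels$block)) {
    rows <- which(labels$block == b)
    rows <- rows[order(labels$trial[rows])]
    nb <- length(rows)
    if (nb < k) {
      stop(sprintf("block %s has %d trials, fewer than k = %d", b, nb, k),
           call. = FALSE)
    }
    sizes <- rep(nb %/% k, k)
    rem <- nb %% k
    if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    stops <- cumsum(sizes)
    starts <- c(1L, head(stops, -1L) + 1L)
    for (i in seq_len(k)) {
      testPos <- starts[i]:stops[i]
      trainPos <- setdiff(seq_len(nb), testPos)
      keep <- vapply(testPos, function(t) {
        min(abs(t - trainPos)) > buffer
      }, logical(1))
      folds[[i]]$train <- c(folds[[i]]$train, rows[trainPos])
      folds[[i]]$test <- c(folds[[i]]$test, rows[testPos[keep]])
    }
  }
  new("CVPlan", k = k, buffer = buffer, folds = folds, nTrials = n)
}

#' Standardized mean squared error
#'
#' Mean squared error divided by the population variance (divide by n) of
#' the true values, so a constant predictor at the truth's mean scores
#' exactly 1 and a perfect predictor 0.
#'
#' @param truth,predictions Numeric vectors of equal length (>= 2).
#' @return Scalar sMSE, or NA with a warning when the truth has zero
#'   variance.
#' @export
smse <- function(truth, predictions) {
  stopifnot(length(truth) == length(predictions), length(truth) >= 2L)
  v <- popVar(truth)
  if (v == 0) {
    warning("truth has zero variance; sMSE undefined")
    return(NA_real_)
  }
  mean((truth - predictions)^2) / v
}

#' Pearson correlation between truth and predictions
#'
#' @param truth,predictions Numeric vectors of equal length.
#' @return Product-moment correlation, or NA with a warning when either
#'   input is constant.
#' @export
pearsonR <- function(truth, predictions) {
  stopifnot(length(truth) == length(predictions))
  if (stats::sd(truth) == 0 || stats::sd(predictions) == 0) {
    warning("constant input; correlation undefined")
    return(NA_real_)
  }
  stats::cor(truth, predictions)
}

#' Discretize continuous predictions to the nearest training label
#'
#' Each prediction is mapped to the nearest label observed in the training
#' set (a prediction of 2.4 with labels 1, 2, 3 becomes 2); ties go to the
#' smaller label.
#'
#' @param predictions Numeric vector.
#' @param trainingLabels Labels seen in training (any numeric vector).
#' @return Numeric vector of discrete labels.
#' @export
discretizePredictions <- function(predictions, trainingLabels) {
  u <- sort(unique(as.numeric(trainingLabels)))
  if (length(u) == 0L) stop("training label set is empty", call. = FALSE)
  dist <- abs(outer(predictions, u, `-`))
  u[max.col(-dist, ties.method = "first")]
}

#' Classification accuracy of discretized predictions
#'
#' @param truth True labels.
#' @param labels Discretized predicted labels.
#' @return Proportion correct in [0, 1].
#' @export
classificationAccuracy <- function(truth, labels) {
  stopifnot(length(truth) == length(labels))
  mean(truth == labels)
}

metricsFor <- function(truth, pred, trainLabels) {
  disc <- discretizePredictions(pred, trainLabels)
  list(smse = smse(truth, pred), r = pearsonR(truth, pred),
       accuracy = classificationAccuracy(truth, disc))
}

#' Run blocked cross-validation for GPR or the MLR baseline
#'
#' Per fold: fits the z-scoring normalizer on the training rows only,
#' normalizes both sets with the training statistics, trains the model on
#' the training rows and predicts the retained (buffered) test rows.
#' Pooled metrics are computed on the concatenation of all folds'
#' (truth, prediction) pairs; per-fold metrics are also reported. Folds
#' with an empty retained test set are skipped with a warning.
#'
#' @param features A [WorkloadFeatures-class].
#' @param plan A [CVPlan-class] over the same trials.
#' @param method `"gpr"` or `"mlr"`.
#' @param labelKind `"level"` (task load N) or `"subjective"` (the block's
#'   1-7 rating, assigned to every trial of the block).
#' @param maxEvals GP optimization budget per fold (default 100).
#' @param lengthScale,signalVar,noiseVar GP hyperparameter initialization
#'   (defaults 10, 1, 1).
#' @param keepModels Keep per-fold fitted models and normalized test data
#'   (needed by [featureSweep()] and [montageSubsetEval()]; default TRUE).
#' @return A [CvResult-class].
#' @export
runCv <- function(features, plan, method = c("gpr", "mlr"),
                  labelKind = c("level", "subjective"), maxEvals = 100L,
                  lengthScale = 10, signalVar = 1, noiseVar = 1,
                  keepModels = TRUE) {
  method <- match.arg(method)
  labelKind <- match.arg(labelKind)
  lab <- trialLabels(features)
  X <- featureValues(features)
  stopifnot(nrow(X) == plan@nTrials)
  y <- switch(labelKind, level = as.numeric(lab$level),
              subjective = as.numeric(lab$rating))
  if (anyNA(y)) stop("labels contain NA for labelKind = ", labelKind,
                     call. = FALSE)

  predRows <- list()
  perFold <- list()
  models <- vector("list", plan@k)
  for (i in seq_len(plan@k)) {
    tr <- plan@folds[[i]]$train
    te <- plan@folds[[i]]$test
    if (length(te) == 0L) {
      warning(sprintf("fold %d has an empty retained test set; skipped", i))
      next
    }
    norm <- fitNormalizer(X[tr, , drop = FALSE])
    Xtr <- applyNormalizer(X[tr, , drop = FALSE], norm)
    Xte <- applyNormalizer(X[te, , drop = FALSE], norm)
    if (method == "gpr") {
      model <- trainGpr(Xtr, y[tr], lengthScale = lengthScale,
                        signalVar = signalVar, noiseVar = noiseVar,
                        maxEvals = maxEvals)
    } else {
      model <- fitMlr(Xtr, y[tr])
    }
    ps <- predict(model, Xte, truth = y[te])
    predRows[[length(predRows) + 1L]] <- data.frame(
      fold = i, row = te, mode = lab$mode[te], level = lab$level[te],
      block = lab$block[te], trial = lab$trial[te], truth = y[te],
      prediction = ps@mean, varLatent = ps@varLatent, varObs = ps@varObs,
      stringsAsFactors = FALSE)
    m <- metricsFor(y[te], ps@mean, y[tr])
    perFold[[length(perFold) + 1L]] <-
      data.frame(fold = i, nTest = length(te), smse = m$smse, r = m$r,
                 accuracy = m$accuracy)
    if (keepModels) {
      models[[i]] <- list(model = model, normalizer = norm, Xte = Xte,
                          yte = y[te], ytrain = y[tr], test = te)
    }
  }
  if (!length(predRows)) stop("all folds were skipped", call. = FALSE)
  predictions <- do.call(rbind, predRows)
  pooled <- metricsFor(predictions$truth, predictions$prediction, y)
  new("CvResult", predictions = predictions, pooled = pooled,
      perFold = do.call(rbind, perFold), models = models,
      method = method, labelKind = labelKind, plan = plan)
}

#' sMSE as a function of retained-feature percentage
#'
#' For each percentage, retains that fraction of features with the
#' shortest trained length scales (ranked per fold, from that fold's
#' training data only) and re-evaluates the fold's test set via
#' [predictWithFeatureSubset()] without refitting; the per-fold sMSE is
#' averaged across folds. Percentages yielding zero features are skipped.
#' The 100% point reproduces the full model's predictions exactly.
#'
#' @param cv A [CvResult-class] from [runCv()] with `method = "gpr"` and
#'   kept models.
#' @param percents Percentages to evaluate (default 1..100 step 1).
#' @return data.frame with columns `percent`, `nFeatures`, `smse`.
#' @export
featureSweep <- function(cv, percents = 1:100) {
  stopifnot(is(cv, "CvResult"), cv@method == "gpr")
  folds <- Filter(Negate(is.null), cv@models)
  if (!length(folds)) stop("runCv must be called with keepModels = TRUE",
                           call. = FALSE)
  d <- length(folds[[1]]$model@featureNames)
  rankings <- lapply(folds, function(f) lengthScales(f$model))
  out <- lapply(percents, function(p) {
    nf <- floor(p / 100 * d)
    if (nf < 1L) return(NULL)
    sm <- vapply(seq_along(folds), function(j) {
      f <- folds[[j]]
      keep <- which(rankings[[j]]$rank <= nf)
      ps <- predictWithFeatureSubset(f$model, f$Xte, keep)
      smse(f$yte, ps@mean)
    }, numeric(1))
    data.frame(percent = p, nFeatures = nf, smse = mean(sm))
  })
  do.call(rbind, out)
}

#' Evaluate a reduced electrode montage
#'
#' Restricts the feature set to all bands at the named channels and
#' re-evaluates each fold's test set through the trained full models
#' without refitting.
#'
#' @param cv A [CvResult-class] (GPR, kept models).
#' @param features The [WorkloadFeatures-class] the CV was run on (source
#'   of the channel annotation).
#' @param channels Either a name from [montageSubsets()] or a character
#'   vector of channel names.
#' @return List with `channels`, `nFeatures`, pooled `smse`, `r` and
#'   `accuracy`.
#' @export
montageSubsetEval <- function(cv, features, channels) {
  stopifnot(is(cv, "CvResult"), cv@method == "gpr")
  if (length(channels) == 1L && channels %in% names(montageSubsets())) {
    channels <- montageSubsets()[[channels]]
  }
  rd <- SummarizedExperiment::rowData(features)
  unknown <- setdiff(channels, unique(rd$channel))
  if (length(unknown)) {
    stop("unknown channel(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  keep <- which(rd$channel %in% channels)
  folds <- Filter(Negate(is.null), cv@models)
  truth <- numeric(0); pred <- numeric(0); ytrainAll <- numeric(0)
  for (f in folds) {
    ps <- predictWithFeatureSubset(f$model, f$Xte, keep)
    truth <- c(truth, f$yte); pred <- c(pred, ps@mean)
    ytrainAll <- c(ytrainAll, f$ytrain)
  }
  m <- metricsFor(truth, pred, ytrainAll)
  c(list(channels = channels, nFeatures = length(keep)), m)
}

#' Cross-task-variant transfer matrix
#'
#' For every ordered (training variant, test variant) pair, fold i pairs
#' the training trials of the training variant with the retained test
#' trials of the test variant (same CV plan throughout); predictions are
#' pooled over folds into one sMSE per cell. Diagonal cells are
#' matched-variant evaluations; off-diagonal cells measure transfer.
#'
#' @inheritParams runCv
#' @return 3 x 3 numeric matrix of pooled sMSE, rows = training variant,
#'   columns = test variant.
#' @export
crossVariantEval <- function(features, plan, labelKind = c("level", "subjective"),
                             maxEvals = 100L) {
  labelKind <- match.arg(labelKind)
  lab <- trialLabels(features)
  X <- featureValues(features)
  y <- switch(labelKind, level = as.numeric(lab$level),
              subjective = as.numeric(lab$rating))
  modes <- TASK_MODES
  cells <- array(list(), dim = c(3, 3))
  for (i in seq_len(plan@k)) {
    tr <- plan@folds[[i]]$train
    te <- plan@folds[[i]]$test
    for (a in seq_along(modes)) {
      trA <- tr[lab$mode[tr] == modes[a]]
      if (length(trA) < 2L) next
      norm <- fitNormalizer(X[trA, , drop = FALSE])
      model <- trainGpr(applyNormalizer(X[trA, , drop = FALSE], norm),
                        y[trA], maxEvals = maxEvals)
      for (b in seq_along(modes)) {
        teB <- te[lab$mode[te] == modes[b]]
        if (!length(teB)) next
        ps <- predict(model, applyNormalizer(X[teB, , drop = FALSE], norm))
        cells[[a, b]] <- rbind(cells[[a, b]],
                               cbind(truth = y[teB], pred = ps@mean))
      }
    }
  }
  out <- matrix(NA_real_, 3, 3, dimnames = list(train = modes, test = modes))
  for (a in 1:3) for (b in 1:3) {
    cell <- cells[[a, b]]
    if (!is.null(cell) && nrow(cell) >= 2L) {
      out[a, b] <- smse(cell[, "truth"], cell[, "pred"])
    }
  }
  out
}
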