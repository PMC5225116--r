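test_that("the CV plan partitions blocks and buffers the test set only", {
  lab <- blockLabels(nBlocks = 1L, nTrials = 100L)
  plan <- makeCvPlan(lab, k = 5L, buffer = 5L)
  # edge partition (trials 1-20): trials 16-20 are within 5 of training
  # trial 21, leaving 15; interior partitions keep the middle 10
  expect_equal(lengths(lapply(plan@folds, `[[`, "test")),
               c(15L, 10L, 10L, 10L, 15L))
  expect_true(all(vapply(plan@folds, function(f) length(f$train), integer(1)) == 80L))
  expect_equal(sort(plan@folds[[1]]$test), 1:15)
  expect_equal(sort(plan@folds[[2]]$test), 26:35)
  expect_no_leakage(plan, lab)
  # every trial appears in exactly one unbuffered test partition
  expect_error(makeCvPlan(blockLabels(1L, 4L), k = 5L), "fewer than k")
})

test_that("uneven block lengths put the remainder in earlier partitions", {
  lab <- blockLabels(nBlocks = 2L, nTrials = 53L)
  plan <- makeCvPlan(lab, k = 5L, buffer = 2L)
  sizes <- diff(c(0, cumsum(c(11, 11, 11, 10, 10))))
  expect_equal(sizes, c(11, 11, 11, 10, 10))
  expect_no_leakage(plan, lab)
  for (f in plan@folds) expect_length(intersect(f$train, f$test), 0L)
})

test_that("sMSE follows its definitional identities", {
  truth <- c(1, 2, 3)
  expect_equal(smse(truth, truth), 0)
  expect_equal(smse(truth, rep(mean(truth), 3)), 1)  # naive model, exactly
  expect_equal(smse(truth, c(1, 1, 3)), 0.5)         # MSE 1/3 over popvar 2/3
  expect_warning(bad <- smse(c(2, 2, 2), c(1, 2, 3)), "zero variance")
  expect_true(is.na(bad))
})

test_that("correlation and discretization behave at their edge cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearsonR(x, x), 1)
  expect_equal(pearsonR(x, -x), -1)
  set.seed(1)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(pearsonR(a, b),
               mean((a - mean(a)) * (b - mean(b))) /
                 (sqrt(mean((a - mean(a))^2)) * sqrt(mean((b - mean(b))^2))),
               tolerance = 1e-12)
  expect_warning(expect_true(is.na(pearsonR(rep(1, 4), x))))
  expect_equal(discretizePredictions(c(2.4, 0.2, 1.5, 3.9), 1:3),
               c(2, 1, 1, 3))
  expect_equal(classificationAccuracy(c(1, 2, 3), c(1, 2, 2)), 2 / 3)
})

test_that("cross-validation trains on informative features and not on noise", {
  planted <- plantedFeatureSet(11L, nBlocks = 3L, nTrials = 100L, d = 6L,
                               nRel = 2L, slope = 1, noise = 0.5)
  plan <- makeCvPlan(trialLabels(planted))
  cv <- runCv(planted, plan, method = "gpr", maxEvals = 30L)
  expect_lt(cv@pooled$smse, 0.5)
  expect_gt(cv@pooled$r, 0.7)
  null <- plantedFeatureSet(12L, nBlocks = 3L, nTrials = 100L, d = 6L,
                            nRel = 0L)
  cv0 <- runCv(null, plan, method = "gpr", maxEvals = 30L, keepModels = FALSE)
  expect_gt(cv0@pooled$smse, 0.7)
  expect_lt(cv0@pooled$smse, 1.5)
  expect_gt(cv0@pooled$smse, cv@pooled$smse)
  # pooled metrics are the metrics of the concatenated predictions
  expect_equal(cv@pooled$smse,
               smse(cv@predictions$truth, cv@predictions$prediction))
  expect_equal(cv@pooled$r,
               pearsonR(cv@predictions$truth, cv@predictions$prediction))
  # pooled and mean-over-folds sMSE are close on balanced folds
  expect_lt(abs(cv@pooled$smse - mean(cv@perFold$smse)), 0.1)
  # the MLR baseline runs through the same plumbing
  cvm <- runCv(planted, plan, method = "mlr", keepModels = FALSE)
  expect_lt(cvm@pooled$smse, 0.7)
})

test_that("per-fold normalization derives from that fold's training rows only", {
  planted <- plantedFeatureSet(13L, nBlocks = 2L, nTrials = 60L, d = 4L)
  plan <- makeCvPlan(trialLabels(planted))
  cv <- runCv(planted, plan, method = "mlr")
  X <- featureValues(planted)
  for (i in seq_along(cv@models)) {
    f <- cv@models[[i]]
    if (is.null(f)) next
    redo <- fitNormalizer(X[cv@plan@folds[[i]]$train, , drop = FALSE])
    expect_equal(f$normalizer@mean, redo@mean)
    expect_equal(f$normalizer@sd, redo@sd)
  }
})

test_that("subjective labels assign the block rating to every trial", {
  planted <- plantedFeatureSet(14L, nBlocks = 3L, nTrials = 60L, d = 4L,
                               nRel = 2L)
  plan <- makeCvPlan(trialLabels(planted))
  cv <- runCv(planted, plan, method = "mlr", labelKind = "subjective",
              keepModels = FALSE)
  lab <- trialLabels(planted)
  expect_setequal(unique(cv@predictions$truth), unique(2 * lab$level))
})

test_that("the feature sweep's 100% point equals the full model", {
  planted <- plantedFeatureSet(15L, nBlocks = 3L, nTrials = 100L, d = 6L,
                               nRel = 2L)
  plan <- makeCvPlan(trialLabels(planted))
  cv <- runCv(planted, plan, method = "gpr", maxEvals = 30L)
  sw <- featureSweep(cv, percents = c(50, 100))
  expect_equal(sw$smse[sw$percent == 100], mean(cv@perFold$smse),
               tolerance = 1e-10)
  expect_equal(sw$nFeatures, c(3L, 6L))
  # percentages below one feature are skipped
  sw2 <- featureSweep(cv, percents = c(10, 100))
  expect_equal(sw2$percent, 100)
})

test_that("montage subsets restrict to all bands at the named channels", {
  # full-montage feature set built directly (no spectral stage needed)
  chans <- actiCapMontage()
  fn <- as.vector(t(outer(chans, defaultBands()$band, paste, sep = ".")))
  lab <- blockLabels(nBlocks = 3L, nTrials = 60L)
  set.seed(16)
  X <- matrix(rnorm(nrow(lab) * length(fn)), nrow(lab), length(fn))
  X[, fn == "O1.gamma"] <- (lab$level - 2) + rnorm(nrow(lab), sd = 0.5)
  colnames(X) <- fn
  feats <- wfFromMatrix(X, lab)
  plan <- makeCvPlan(lab)
  cv <- runCv(feats, plan, method = "gpr", maxEvals = 0L)
  for (nm in c(balert = "balert", emotiv = "emotiv", occipital = "occipital")) {
    res <- montageSubsetEval(cv, feats, nm)
    expect_equal(res$nFeatures, 6L * length(montageSubsets()[[nm]]))
  }
  expect_equal(montageSubsetEval(cv, feats, "emotiv")$nFeatures, 96L)
  expect_equal(montageSubsetEval(cv, feats, "balert")$nFeatures, 54L)
  expect_equal(montageSubsetEval(cv, feats, "occipital")$nFeatures, 30L)
  expect_error(montageSubsetEval(cv, feats, c("O1", "Nope")), "unknown")
})

test_that("the cross-variant matrix has nine cells indexed train x test", {
  lab <- blockLabels(nBlocks = 9L, nTrials = 60L,
                     modes = rep(c("Auditory", "Numeric", "Spatial"),
                                 each = 3L))
  set.seed(17)
  X <- matrix(rnorm(nrow(lab) * 4), nrow(lab), 4)
  X[, 1] <- (lab$level - 2) + rnorm(nrow(lab), sd = 0.4)
  colnames(X) <- paste0("Ch", 1:4, ".band")
  feats <- wfFromMatrix(X, lab)
  plan <- makeCvPlan(lab)
  cvm <- crossVariantEval(feats, plan, maxEvals = 10L)
  expect_equal(dim(cvm), c(3L, 3L))
  expect_false(anyNA(cvm))
  # a mode-independent signal transfers: every cell clearly beats naive
  expect_true(all(cvm < 0.9))
})
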