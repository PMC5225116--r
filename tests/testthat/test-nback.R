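test_that("stimulus generation matches the task's probabilistic structure", {
  b <- generateBlock("Numeric", 2L, 100000L, seed = 101L)
  tr <- b@trials
  eligible <- tr$index > 2L
  pMatch <- 1 - (7 / 8)^2                       # 0.234375
  se <- sqrt(pMatch * (1 - pMatch) / sum(eligible))
  expect_lt(abs(mean(tr$isMatch[eligible]) - pMatch), 3 * se)
  seF <- sqrt((1 / 8) * (7 / 8) / sum(eligible))
  expect_lt(abs(mean(tr$forced[eligible]) - 1 / 8), 3 * seF)
  # forced implies match; early trials never match
  expect_true(all(tr$isMatch[tr$forced]))
  expect_false(any(tr$isMatch[tr$index <= 2L]))
  expect_true(all(tr$stimulus %in% 1:8))
})

test_that("blocks shorter than N have no matches and generation is deterministic", {
  b <- generateBlock("Spatial", 3L, 3L, seed = 5L)
  expect_false(any(b@trials$isMatch))
  b1 <- generateBlock("Auditory", 1L, 50L, seed = 9L)
  b2 <- generateBlock("Auditory", 1L, 50L, seed = 9L)
  expect_identical(b1@trials, b2@trials)
  expect_error(generateBlock("Auditory", 5L, 10L, seed = 1L), "level")
  expect_error(generateBlock("Auditory", 1L, 0L, seed = 1L), "positive")
  expect_error(generateBlock("Visual", 1L, 10L, seed = 1L), "mode")
})

test_that("a default session has 9 blocks of 100 trials with ascending levels", {
  s <- generateSession("P01", seed = 3L)
  tr <- sessionTrials(s)
  expect_equal(nrow(tr), 900L)
  expect_equal(length(s@blocks), 9L)
  modes <- vapply(s@blocks, function(b) b@mode, character(1))
  levels <- vapply(s@blocks, function(b) b@level, integer(1))
  expect_equal(levels, rep(1:3, 3))
  expect_setequal(unique(modes), c("Auditory", "Numeric", "Spatial"))
  # small sessions scale arithmetically
  s2 <- generateSession(nTrials = 10L, seed = 3L)
  expect_equal(nrow(sessionTrials(s2)), 90L)
  # same structure, different stimuli under a different seed
  s3 <- generateSession("P01", seed = 4L)
  expect_equal(vapply(s3@blocks, function(b) b@mode, character(1)), modes)
  expect_false(identical(sessionTrials(s3)$stimulus, tr$stimulus))
  # counterbalancing rotates mode order with participant index
  s4 <- generateSession("P02", participantIndex = 2L, seed = 3L)
  expect_false(identical(s4@modeOrder, s@modeOrder))
})

test_that("response simulation follows the hit and false-alarm probabilities", {
  b <- generateBlock("Auditory", 2L, 400L, seed = 21L)
  ideal <- simulateResponses(b, list(hitProb = rep(1, 3), faProb = rep(0, 3)),
                             seed = 1L)
  expect_identical(ideal@trials$responded, ideal@trials$isMatch)
  mute <- simulateResponses(b, list(hitProb = rep(0, 3), faProb = rep(0, 3)),
                            seed = 1L)
  expect_false(any(mute@trials$responded))
  coin <- simulateResponses(b, list(hitProb = rep(0.5, 3), faProb = rep(0.5, 3)),
                            seed = 2L)
  expect_lt(abs(mean(coin@trials$responded) - 0.5), 3 * sqrt(0.25 / 400))
  expect_error(
    simulateResponses(b, list(hitProb = rep(2, 3), faProb = rep(0, 3)), seed = 1L),
    "probabilities")
})

test_that("block accuracy is TP/(TP+FP+FN) with its degenerate cases", {
  b <- generateBlock("Numeric", 1L, 200L, seed = 31L)
  perfect <- simulateResponses(b, list(hitProb = rep(1, 3), faProb = rep(0, 3)),
                               seed = 1L)
  expect_equal(blockAccuracy(perfect), 1)
  silent <- simulateResponses(b, list(hitProb = rep(0, 3), faProb = rep(0, 3)),
                              seed = 1L)
  expect_equal(blockAccuracy(silent), 0)
  # respond-all accuracy equals the block's match frequency
  all <- simulateResponses(b, list(hitProb = rep(1, 3), faProb = rep(1, 3)),
                           seed = 1L)
  expect_equal(blockAccuracy(all), mean(b@trials$isMatch))
  # undefined ratio: no matches, no responses
  short <- generateBlock("Numeric", 3L, 3L, seed = 1L)
  short <- simulateResponses(short, list(hitProb = rep(0, 3), faProb = rep(0, 3)),
                             seed = 1L)
  expect_warning(acc <- blockAccuracy(short), "undefined")
  expect_true(is.na(acc))
  expect_error(blockAccuracy(generateBlock("Numeric", 1L, 5L, seed = 1L)),
               "responses")
})

test_that("subjective ratings sit in 1..7 and increase with level on average", {
  b <- generateBlock("Spatial", 2L, 10L, seed = 41L)
  degenerate <- matrix(0, 3, 7); degenerate[, 4] <- 1
  expect_equal(rateSubjectiveWorkload(b, degenerate, seed = 1L)@rating, 4L)
  expect_equal(rateSubjectiveWorkload(b, seed = 7L)@rating,
               rateSubjectiveWorkload(b, seed = 7L)@rating)
  means <- vapply(1:3, function(lv) {
    bb <- generateBlock("Spatial", lv, 5L, seed = 42L)
    mean(vapply(1:200, function(s)
      rateSubjectiveWorkload(bb, seed = s)@rating, integer(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_true(all(means >= 1 & means <= 7))
})

test_that("sessions round-trip through the CSV record format", {
  s <- generateSession(nTrials = 12L, seed = 8L)
  path <- withr::local_tempfile(fileext = ".csv")
  writeSessionCsv(s, path)
  back <- readSessionCsv(path)
  orig <- sessionTrials(s)
  expect_equal(names(back), names(orig))
  expect_equal(back$stimulus, orig$stimulus)
  expect_equal(back$isMatch, orig$isMatch)
})
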