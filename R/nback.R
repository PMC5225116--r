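## N-back task simulator.
##
## Stimulus generation follows the task's stated probabilistic structure:
## each trial's stimulus is drawn uniformly from 8 alternatives, then, for
## trials deeper than N into the block, the draw is independently overwritten
## with the stimulus N back with probability 1/8 (a "forced" match). The
## resulting long-run match probability for eligible trials is
## 1/8 + 7/8 * 1/8 = 1 - (7/8)^2 = 23.44%.

#' Generate one N-back block
#'
#' @param mode Stimulus mode: "Auditory", "Numeric" or "Spatial".
#' @param level Task level N in 1..3.
#' @param nTrials Number of comparison trials (default 100).
#' @param seed Integer seed; the block is a pure function of the arguments.
#' @return An [NBackBlock-class] with `responded` unset (NA).
#' @details The forced overwrite uses the final value of the stimulus N
#'   positions back, so overwrites chain through the sequence; `isMatch` is
#'   computed from the final stimulus sequence. Trials with index <= N are
#'   never matches and never forced.
#' @export
#' @examples
#' b <- generateBlock("Auditory", 2L, 100L, seed = 1L)
#' mean(sessionTrials(b)$isMatch)
generateBlock <- function(mode, level, nTrials = 100L, seed) {
  assertScalarIn(mode, TASK_MODES, "mode")
  if (length(level) != 1L || !level %in% 1:3) {
    stop("level must be a single value in 1..3", call. = FALSE)
  }
  nTrials <- as.integer(nTrials)
  if (is.na(nTrials) || nTrials < 1L) {
    stop("nTrials must be a positive count", call. = FALSE)
  }
  level <- as.integer(level)

  withr::with_seed(as.integer(seed), {
    draws <- sample.int(N_STIMULI, nTrials, replace = TRUE)
    idx <- seq_len(nTrials)
    forced <- runif(nTrials) < FORCED_MATCH_PROB & idx > level
    ## Resolve chained overwrites: within each residue class mod N the
    ## final stimulus is the most recent non-forced draw at or before it.
    stim <- draws
    if (any(forced)) {
      for (r in seq_len(min(level, nTrials))) {
        chain <- seq.int(r, nTrials, by = level)
        keep <- !forced[chain]
        src <- cummax(ifelse(keep, seq_along(chain), 0L))
        stim[chain] <- draws[chain[src]]
      }
    }
    isMatch <- c(rep(FALSE, min(level, nTrials)),
                 stim[idx[idx > level]] == stim[idx[idx > level] - level])
    trials <- data.frame(index = idx, stimulus = stim, isMatch = isMatch,
                         forced = forced, responded = NA)
    new("NBackBlock", mode = mode, level = level, trials = trials)
  })
}

#' Generate a full N-back session
#'
#' At defaults this produces the canonical session layout: one 100-trial
#' block per (mode, level) cell, levels ascending 1,2,3 within each mode,
#' for 9 blocks and 900 trials in total. Mode order is counterbalanced
#' across participants by a Latin square over the three modes, selected by
#' the participant index.
#'
#' @param participant Participant label (also selects the mode-order row
#'   when `participantIndex` is not given).
#' @param participantIndex 1-based index into the Latin-square
#'   counterbalancing scheme (default 1).
#' @param blocksPerCell Blocks per (mode, level) combination (default 1).
#' @param nTrials Trials per block (default 100).
#' @param seed Integer seed.
#' @return An [NBackSession-class].
#' @export
#' @examples
#' s <- generateSession("P01", seed = 1L)
#' nrow(sessionTrials(s))
generateSession <- function(participant = "P01", participantIndex = 1L,
                            blocksPerCell = 1L, nTrials = 100L, seed) {
  blocksPerCell <- as.integer(blocksPerCell)
  stopifnot(blocksPerCell >= 1L)
  square <- rbind(TASK_MODES,
                  TASK_MODES[c(2, 3, 1)],
                  TASK_MODES[c(3, 1, 2)])
  modeOrder <- square[(as.integer(participantIndex) - 1L) %% 3L + 1L, ]
  nBlocks <- 3L * 3L * blocksPerCell
  seeds <- spawnSeeds(seed, nBlocks)
  blocks <- vector("list", nBlocks)
  i <- 0L
  for (m in modeOrder) {
    for (lv in 1:3) {
      for (rep in seq_len(blocksPerCell)) {
        i <- i + 1L
        blocks[[i]] <- generateBlock(m, lv, nTrials, seeds[i])
      }
    }
  }
  new("NBackSession", participant = as.character(participant),
      blocks = blocks, modeOrder = modeOrder)
}

#' Simulate button-press responses for a block
#'
#' Responses are drawn independently per trial: with probability
#' `hitProb[level]` on match trials and `faProb[level]` on non-match
#' trials.
#'
#' @param block An [NBackBlock-class].
#' @param responseModel Named list with numeric vectors `hitProb` and
#'   `faProb` indexed by level (length 3), all probabilities in [0, 1].
#' @param seed Integer seed.
#' @return The block with `responded` populated.
#' @export
simulateResponses <- function(block, responseModel = defaultResponseModel(),
                              seed) {
  hp <- responseModel$hitProb[block@level]
  fp <- responseModel$faProb[block@level]
  if (anyNA(c(hp, fp)) || any(c(hp, fp) < 0) || any(c(hp, fp) > 1)) {
    stop("response probabilities must be in [0, 1]", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    u <- runif(nrow(block@trials))
    block@trials$responded <- ifelse(block@trials$isMatch, u < hp, u < fp)
  })
  block
}

#' Default response model
#'
#' Hit and false-alarm probabilities by task level for the simulated
#' responder. These are plumbing defaults chosen to decline plausibly with
#' load; they carry no ground-truth status.
#'
#' @return Named list with `hitProb` and `faProb`, each length 3.
#' @export
defaultResponseModel <- function() {
  list(hitProb = c(0.95, 0.85, 0.70), faProb = c(0.02, 0.05, 0.10))
}

#' Block accuracy TP / (TP + FP + FN)
#'
#' True positives are responses on match trials, false positives responses
#' on non-match trials, false negatives missed matches. Responding on every
#' trial yields the match frequency (chance ceiling 23.44% in the long
#' run); never responding yields 0. When the denominator is zero (no match
#' trials and no responses) the ratio is undefined and NA is returned with
#' a warning.
#'
#' @param block An [NBackBlock-class] with responses populated.
#' @return Proportion in [0, 1], or NA.
#' @export
blockAccuracy <- function(block) {
  tr <- block@trials
  if (anyNA(tr$responded)) {
    stop("responses are not populated; run simulateResponses() first",
         call. = FALSE)
  }
  tp <- sum(tr$responded & tr$isMatch)
  fp <- sum(tr$responded & !tr$isMatch)
  fn <- sum(!tr$responded & tr$isMatch)
  if (tp + fp + fn == 0L) {
    warning("accuracy undefined: no matches and no responses")
    return(NA_real_)
  }
  tp / (tp + fp + fn)
}

#' Draw a subjective workload rating for a block
#'
#' Ratings are on a 1-7 Likert scale from low to high workload. The rating
#' model gives, per level, a probability distribution over the 7 points;
#' the default model centers on 2, 4 and 6 for levels 1, 2 and 3 so that
#' mean rating increases with N.
#'
#' @param block An [NBackBlock-class].
#' @param ratingModel 3 x 7 matrix of probabilities, rows = levels.
#' @param seed Integer seed.
#' @return The block with `rating` set (integer in 1..7).
#' @export
rateSubjectiveWorkload <- function(block, ratingModel = defaultRatingModel(),
                                   seed) {
  p <- ratingModel[block@level, ]
  stopifnot(length(p) == 7L, all(p >= 0), sum(p) > 0)
  r <- withr::with_seed(as.integer(seed), sample.int(7L, 1L, prob = p))
  block@rating <- min(max(r, 1L), 7L)
  block
}

#' Default subjective-rating model
#'
#' @return 3 x 7 matrix of rating probabilities (rows = level 1..3),
#'   discretized normals centered at 2, 4, 6 with SD 1.
#' @export
defaultRatingModel <- function() {
  centers <- c(2, 4, 6)
  m <- t(vapply(centers, function(mu) {
    w <- exp(-0.5 * ((1:7 - mu) / 1)^2)
    w / sum(w)
  }, numeric(7)))
  rownames(m) <- paste0("level", 1:3)
  m
}

## ---- accessors & serialization -----------------------------------------

#' @describeIn sessionTrials trials of a single block
#' @export
setMethod("sessionTrials", "NBackBlock", function(x) {
  cbind(mode = x@mode, level = x@level, x@trials,
        rating = x@rating, stringsAsFactors = FALSE)
})

#' @describeIn sessionTrials all trials of a session, with block numbering
#' @export
setMethod("sessionTrials", "NBackSession", function(x) {
  if (!length(x@blocks)) {
    return(data.frame(participant = character(), mode = character(),
                      level = integer(), block = integer(),
                      trial = integer(), stimulus = integer(),
                      isMatch = logical(), forced = logical(),
                      responded = logical(), rating = integer()))
  }
  out <- do.call(rbind, lapply(seq_along(x@blocks), function(i) {
    b <- x@blocks[[i]]
    data.frame(participant = x@participant, mode = b@mode,
               level = b@level, block = i, trial = b@trials$index,
               stimulus = b@trials$stimulus, isMatch = b@trials$isMatch,
               forced = b@trials$forced, responded = b@trials$responded,
               rating = b@rating, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
})

#' Write / read a session as CSV
#'
#' One record per trial with the documented column order: participant,
#' mode, level, block, trial, stimulus, isMatch, forced, responded, rating.
#'
#' @param session An [NBackSession-class].
#' @param path File path.
#' @return `writeSessionCsv` returns `path` invisibly; `readSessionCsv`
#'   returns the trial data.frame.
#' @export
writeSessionCsv <- function(session, path) {
  write.csv(sessionTrials(session), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSessionCsv
#' @export
readSessionCsv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
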