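# Shared fixture builders. Everything is generated in code at test time.

# WorkloadFeatures directly from a trials x features matrix, bypassing the
# spectral stage; used where only the evaluation machinery is under test.
wfFromMatrix <- function(X, labels) {
  stopifnot(nrow(X) == nrow(labels))
  fn <- colnames(X)
  if (is.null(fn)) fn <- paste0("Ch", seq_len(ncol(X)), ".band")
  parts <- strsplit(fn, ".", fixed = TRUE)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(logpower = t(X)),
    rowData = S4Vectors::DataFrame(
      channel = vapply(parts, `[`, character(1), 1L),
      band = vapply(parts, `[`, character(1), 2L)),
    colData = S4Vectors::DataFrame(labels))
  rownames(se) <- fn
  new("WorkloadFeatures", se)
}

# blocked label frame: nBlocks blocks of nTrials, modes cycling
blockLabels <- function(nBlocks = 3L, nTrials = 100L,
                        modes = rep("Auditory", nBlocks),
                        levels = rep(1:3, length.out = nBlocks)) {
  do.call(rbind, lapply(seq_len(nBlocks), function(b) {
    data.frame(participant = "P01", mode = modes[b], level = levels[b],
               block = b, trial = seq_len(nTrials),
               rating = 2L * levels[b], stringsAsFactors = FALSE)
  }))
}

# Synthetic blocked regression problem: level labels drive `nRel` features
# linearly (slope in z units); remaining features are pure noise.
plantedFeatureSet <- function(seed, nBlocks = 3L, nTrials = 100L, d = 6L,
                              nRel = 2L, slope = 1, noise = 0.5) {
  labels <- blockLabels(nBlocks, nTrials)
  n <- nrow(labels)
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * d), n, d)
    if (nRel > 0L) {
      for (j in seq_len(nRel)) {
        X[, j] <- slope * (labels$level - 2) + rnorm(n, sd = noise)
      }
    }
    colnames(X) <- paste0("Ch", seq_len(d), ".band")
    wfFromMatrix(X, labels)
  })
}

expect_no_leakage <- function(plan, labels) {
  for (f in plan@folds) {
    for (b in unique(labels$block)) {
      te <- intersect(f$test, which(labels$block == b))
      tr <- intersect(f$train, which(labels$block == b))
      if (length(te) && length(tr)) {
        dmin <- min(vapply(labels$trial[te],
                           function(t) min(abs(t - labels$trial[tr])),
                           numeric(1)))
        expect_gt(dmin, plan@buffer)
      }
    }
  }
}
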