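## End-to-end pipeline: simulate -> synthesize -> extract -> evaluate.

#' Assemble a validated pipeline configuration
#'
#' Collects every tunable of the four stages with the canonical defaults:
#' one 100-trial block per (mode, level) cell (900 trials), the 32-channel
#' montage with the default beta/gamma relevance signature, the six
#' standard bands, 5-fold blocked CV with a 5-trial buffer, and GP
#' initialization at length scale 10, signal variance 1, noise variance 1
#' with a 100-evaluation budget.
#'
#' @param participants Number of simulated participants.
#' @param nTrials Trials per block.
#' @param blocksPerCell Blocks per (mode, level) cell.
#' @param channels Montage (character vector of channel names).
#' @param relevanceSpec Ground-truth effect map for the synthesizer.
#' @param bands Band definitions.
#' @param noiseSd,broadbandSd Synthesizer noise settings.
#' @param k,buffer CV settings.
#' @param lengthScale,signalVar,noiseVar,maxEvals GP settings.
#' @param methods Models to evaluate (subset of `c("gpr", "mlr")`).
#' @param labelKind `"level"` or `"subjective"`.
#' @param seed Master seed; all stage seeds derive from it.
#' @return Validated configuration list (class `gprloadConfig`).
#' @export
pipelineConfig <- function(participants = 1L, nTrials = 100L,
                           blocksPerCell = 1L,
                           channels = actiCapMontage(),
                           relevanceSpec = defaultRelevanceSpec(channels),
                           bands = defaultBands(), noiseSd = 0.5,
                           broadbandSd = 1.0, k = 5L, buffer = 5L,
                           lengthScale = 10, signalVar = 1, noiseVar = 1,
                           maxEvals = 100L, methods = c("gpr", "mlr"),
                           labelKind = "level", seed = 1L) {
  validateBands(bands)
  stopifnot(participants >= 1L, nTrials >= 1L, blocksPerCell >= 1L,
            k >= 2L, buffer >= 0L, lengthScale > 0, signalVar > 0,
            noiseVar > 0, maxEvals >= 0L,
            all(methods %in% c("gpr", "mlr")),
            labelKind %in% c("level", "subjective"))
  cfg <- list(schema = 1L, participants = as.integer(participants),
              nTrials = as.integer(nTrials),
              blocksPerCell = as.integer(blocksPerCell),
              channels = channels, relevanceSpec = relevanceSpec,
              bands = bands, noiseSd = noiseSd, broadbandSd = broadbandSd,
              k = as.integer(k), buffer = as.integer(buffer),
              lengthScale = lengthScale, signalVar = signalVar,
              noiseVar = noiseVar, maxEvals = as.integer(maxEvals),
              methods = methods, labelKind = labelKind,
              seed = as.integer(seed))
  class(cfg) <- "gprloadConfig"
  cfg
}

#' Run the full pipeline
#'
#' Executes simulate -> synthesize -> extract -> evaluate for every
#' simulated participant and writes, under `outDir`: the session and
#' feature CSVs, a predictions CSV and a metrics JSON per method, plus a
#' manifest stamping the configuration hash and master seed. The whole
#' run is a pure function of (config, seed): identical configurations
#' yield bit-identical feature CSVs.
#'
#' @param config A configuration from [pipelineConfig()].
#' @param outDir Output directory (created if missing).
#' @return Invisibly, a list per participant with the feature container,
#'   CV results per method, and output paths.
#' @export
runPipeline <- function(config, outDir) {
  stopifnot(inherits(config, "gprloadConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stageSeeds <- spawnSeeds(config$seed, 4L * config$participants)
  manifest <- list(configHash = objectHash(config), seed = config$seed,
                   schema = config$schema)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE)
  results <- vector("list", config$participants)
  for (p in seq_len(config$participants)) {
    id <- sprintf("P%02d", p)
    s <- stageSeeds[(p - 1L) * 4L + 1:4]
    session <- tryCatch(
      generateSession(id, participantIndex = p,
                      blocksPerCell = config$blocksPerCell,
                      nTrials = config$nTrials, seed = s[1]),
      error = function(e) stop("stage simulate failed: ", conditionMessage(e),
                               call. = FALSE))
    respSeeds <- spawnSeeds(s[2], 2L * length(session@blocks))
    for (i in seq_along(session@blocks)) {
      session@blocks[[i]] <- simulateResponses(session@blocks[[i]],
                                               seed = respSeeds[2 * i - 1L])
      session@blocks[[i]] <- rateSubjectiveWorkload(session@blocks[[i]],
                                                    seed = respSeeds[2 * i])
    }
    writeSessionCsv(session, file.path(outDir, paste0(id, "_session.csv")))

    profile <- makeParticipantProfile(config$channels, config$bands,
                                      config$relevanceSpec,
                                      noiseSd = config$noiseSd,
                                      broadbandSd = config$broadbandSd,
                                      seed = s[3])
    epochs <- tryCatch(synthesizeSessionEpochs(session, profile, seed = s[4]),
                       error = function(e) stop("stage synthesize failed: ",
                                                conditionMessage(e),
                                                call. = FALSE))
    feats <- tryCatch(extractFeatures(epochs, config$bands),
                      error = function(e) stop("stage extract failed: ",
                                               conditionMessage(e),
                                               call. = FALSE))
    writeFeaturesCsv(feats, file.path(outDir, paste0(id, "_features.csv")))

    plan <- makeCvPlan(trialLabels(feats), k = config$k,
                       buffer = config$buffer)
    cvs <- list()
    for (m in config$methods) {
      cv <- tryCatch(
        runCv(feats, plan, method = m, labelKind = config$labelKind,
              maxEvals = config$maxEvals,
              lengthScale = config$lengthScale,
              signalVar = config$signalVar, noiseVar = config$noiseVar,
              keepModels = FALSE),
        error = function(e) stop("stage evaluate failed: ",
                                 conditionMessage(e), call. = FALSE))
      write.csv(cv@predictions,
                file.path(outDir, sprintf("%s_predictions_%s.csv", id, m)),
                row.names = FALSE)
      jsonlite::write_json(
        c(manifest, cv@pooled, list(method = m, participant = id)),
        file.path(outDir, sprintf("%s_metrics_%s.json", id, m)),
        auto_unbox = TRUE, digits = NA)
      cvs[[m]] <- cv
    }
    results[[p]] <- list(participant = id, features = feats, cv = cvs)
  }
  invisible(list(outDir = outDir, manifest = manifest,
                 participants = results))
}
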