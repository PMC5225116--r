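## Synthetic EEG generator.
##
## Each epoch is a sum, per channel, of six band-limited oscillations (one
## per frequency band, random phase per trial) plus band-limited background
## noise. The controlled quantity is the log band power: for feature
## (channel, band) its mean is baseline + slope * (N - 2) and its
## trial-to-trial SD is noiseSd, both on the natural-log scale. Centering
## the level effect at the middle level makes `baseline` the feature's
## typical value, so features whose slope is specific to one task variant
## rest at their typical value in the other variants. Oscillation amplitudes are
## calibrated against the package's own Welch estimator so that extracted
## log band powers reproduce the generating parameters up to spectral
## estimation error, making parameter recovery through the spectral stage a
## genuine end-to-end test.

EPOCH_SAMPLES <- 750L   # 3 s at 250 Hz
EPOCH_FS <- 250
LEVEL_CENTER <- 2       # slope effects are centered at the middle level

#' Ground-truth relevance specification for the default profile
#'
#' Places nonzero level slopes on beta and gamma band power at lateral
#' temporal and occipital sites, emulating the qualitative observation that
#' higher-frequency features at those sites carry most task-load
#' information. Slope magnitude is a free choice (default 0.25 natural-log
#' units per level step).
#'
#' @param channelNames Montage in use.
#' @param slope Log-power change per unit of N for the relevant features.
#' @param modes Optional character vector: restrict the effect to these
#'   stimulus modes (default: all modes share the signature).
#' @return data.frame with columns `channel`, `band`, `slope`, `mode`
#'   (NA = applies to every mode).
#' @export
defaultRelevanceSpec <- function(channelNames = actiCapMontage(),
                                 slope = 0.25, modes = NA_character_) {
  sites <- intersect(c("T7", "T8", "P7", "P8", "O1", "Oz", "O2"),
                     channelNames)
  grid <- expand.grid(channel = sites, band = c("beta", "gamma"),
                      mode = modes, stringsAsFactors = FALSE)
  grid$slope <- rep_len(slope, nrow(grid))
  grid[, c("channel", "band", "slope", "mode")]
}

#' Build a participant profile for the EEG synthesizer
#'
#' @param channelNames Character vector of channel names.
#' @param bands Band definitions (see [defaultBands()]).
#' @param relevanceSpec data.frame with columns `channel`, `band`, `slope`
#'   and optionally `mode` (NA or absent = all modes); rows name the
#'   (channel, band) features that carry task-level information. An empty
#'   data.frame plants no signal.
#' @param baselineByBand Level-independent mean log band power per band
#'   (recycled across channels); defaults fall off with frequency as real
#'   EEG spectra do.
#' @param noiseSd Trial-to-trial SD of log band power (scalar or
#'   channels x bands matrix), default 0.5.
#' @param broadbandSd SD of the 1-45 Hz background noise in signal units.
#' @param seed Integer seed (controls the small per-channel baseline
#'   jitter that individualizes profiles).
#' @return A [ParticipantProfile-class] recording the generating truth.
#' @export
#' @examples
#' p <- makeParticipantProfile(c("O1", "O2"), seed = 1L,
#'   relevanceSpec = data.frame(channel = "O1", band = "gamma", slope = 0.3))
#' relevantFeatures(p)
makeParticipantProfile <- function(channelNames = actiCapMontage(),
                                   bands = defaultBands(),
                                   relevanceSpec = defaultRelevanceSpec(channelNames),
                                   baselineByBand = c(3.0, 2.5, 2.5, 2.0, 1.5, 1.0),
                                   noiseSd = 0.5, broadbandSd = 1.0, seed) {
  validateBands(bands)
  nc <- length(channelNames)
  nb <- nrow(bands)
  stopifnot(length(baselineByBand) == nb)
  baseline <- withr::with_seed(as.integer(seed), {
    matrix(rep(baselineByBand, each = nc), nc, nb) +
      matrix(rnorm(nc * nb, sd = 0.1), nc, nb)
  })
  dimnames(baseline) <- list(channelNames, bands$band)
  if (is.matrix(noiseSd)) {
    stopifnot(all(dim(noiseSd) == c(nc, nb)))
    nsd <- noiseSd
  } else {
    nsd <- matrix(noiseSd, nc, nb)
  }
  dimnames(nsd) <- dimnames(baseline)
  slopes <- array(0, dim = c(nc, nb, 3L),
                  dimnames = list(channelNames, bands$band, TASK_MODES))
  if (nrow(relevanceSpec)) {
    if (is.null(relevanceSpec$mode)) relevanceSpec$mode <- NA_character_
    bad <- !(relevanceSpec$channel %in% channelNames)
    if (any(bad)) {
      stop("unknown channel(s): ",
           paste(unique(relevanceSpec$channel[bad]), collapse = ", "),
           call. = FALSE)
    }
    bad <- !(relevanceSpec$band %in% bands$band)
    if (any(bad)) {
      stop("unknown band(s): ",
           paste(unique(relevanceSpec$band[bad]), collapse = ", "),
           call. = FALSE)
    }
    for (i in seq_len(nrow(relevanceSpec))) {
      ms <- if (is.na(relevanceSpec$mode[i])) TASK_MODES else relevanceSpec$mode[i]
      if (!all(ms %in% TASK_MODES)) stop("unknown mode in relevanceSpec")
      slopes[relevanceSpec$channel[i], relevanceSpec$band[i], ms] <-
        relevanceSpec$slope[i]
    }
  }
  new("ParticipantProfile", channelNames = channelNames, bands = bands,
      baseline = baseline, slopes = slopes, noiseSd = nsd,
      broadbandSd = broadbandSd)
}

#' Features with nonzero level slope in a profile
#'
#' @param profile A [ParticipantProfile-class].
#' @return Character vector of `<channel>.<band>` feature names that carry
#'   task-level signal in at least one mode.
#' @export
relevantFeatures <- function(profile) {
  rel <- apply(profile@slopes != 0, c(1, 2), any)
  grid <- expand.grid(channel = profile@channelNames,
                      band = profile@bands$band, stringsAsFactors = FALSE)
  keep <- rel[cbind(grid$channel, grid$band)]
  paste0(grid$channel, ".", grid$band)[keep]
}

## Band carrier frequencies: the spectral-bin center nearest the band
## midpoint on the Welch grid, so the oscillation lands on a bin.
bandCarrierFreqs <- function(bands, fs = EPOCH_FS, nfft = 512L) {
  df <- fs / nfft
  round((bands$low + bands$high) / 2 / df) * df
}

## Measured band power of a unit-amplitude carrier through the package's
## own Welch + band-averaging stage; used to calibrate amplitudes.
bandCalibration <- function(bands, fs = EPOCH_FS, nSamples = EPOCH_SAMPLES) {
  fc <- bandCarrierFreqs(bands, fs)
  tt <- (seq_len(nSamples) - 1L) / fs
  vapply(seq_len(nrow(bands)), function(b) {
    p <- welchPsd(cos(2 * pi * fc[b] * tt), fs = fs)
    bandPower(p, bands[b, , drop = FALSE])
  }, numeric(1))
}

## band-limited (1-45 Hz) Gaussian background noise via spectral masking
broadbandNoise <- function(n, fs, sdTarget, lowHz = 1, highHz = 45) {
  z <- stats::fft(rnorm(n))
  f <- pmin(seq_len(n) - 1L, n - (seq_len(n) - 1L)) * fs / n
  z[f < lowHz | f > highHz] <- 0 + 0i
  x <- Re(stats::fft(z, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x * (sdTarget / s)
}

#' Synthesize one epoch
#'
#' @param trial List or one-row data.frame with elements `level` and
#'   `mode`.
#' @param profile A [ParticipantProfile-class].
#' @param seed Integer seed; the epoch is byte-identical for identical
#'   arguments.
#' @param calib Optional precomputed [bandCalibration()] vector (computed
#'   on the fly when NULL).
#' @return Numeric matrix channels x samples (3 s at 250 Hz).
#' @export
synthesizeEpoch <- function(trial, profile, seed, calib = NULL) {
  level <- as.numeric(trial$level)
  mode <- as.character(trial$mode)
  assertScalarIn(mode, TASK_MODES, "mode")
  bands <- profile@bands
  if (is.null(calib)) calib <- bandCalibration(bands)
  fc <- bandCarrierFreqs(bands)
  nc <- length(profile@channelNames)
  nb <- nrow(bands)
  tt <- (seq_len(EPOCH_SAMPLES) - 1L) / EPOCH_FS

  withr::with_seed(as.integer(seed), {
    g <- profile@baseline + profile@slopes[, , mode] * (level - LEVEL_CENTER) +
      matrix(rnorm(nc * nb), nc, nb) * profile@noiseSd
    amp <- sqrt(exp(g) / rep(calib, each = nc))
    phase <- matrix(runif(nc * nb, 0, 2 * pi), nc, nb)
    x <- matrix(0, nc, EPOCH_SAMPLES)
    for (b in seq_len(nb)) {
      x <- x + amp[, b] * cos(outer(phase[, b], 2 * pi * fc[b] * tt, `+`))
    }
    if (profile@broadbandSd > 0) {
      for (ch in seq_len(nc)) {
        x[ch, ] <- x[ch, ] +
          broadbandNoise(EPOCH_SAMPLES, EPOCH_FS, profile@broadbandSd)
      }
    }
    rownames(x) <- profile@channelNames
    x
  })
}

#' Synthesize epochs for every trial of a session
#'
#' @param session An [NBackSession-class].
#' @param profile A [ParticipantProfile-class].
#' @param seed Integer master seed (spawns one child seed per trial).
#' @return An [EpochedSession-class] with labels copied from the session
#'   trials and the generating profile retained.
#' @export
#' @examples
#' s <- generateSession(nTrials = 5L, seed = 1L)
#' p <- makeParticipantProfile(c("O1", "Oz"), seed = 2L,
#'   relevanceSpec = defaultRelevanceSpec(c("O1", "Oz")))
#' es <- synthesizeSessionEpochs(s, p, seed = 3L)
synthesizeSessionEpochs <- function(session, profile, seed) {
  labels <- sessionTrials(session)
  n <- nrow(labels)
  epochs <- array(0, dim = c(n, length(profile@channelNames), EPOCH_SAMPLES))
  if (n > 0L) {
    calib <- bandCalibration(profile@bands)
    seeds <- spawnSeeds(seed, n)
    for (i in seq_len(n)) {
      epochs[i, , ] <- synthesizeEpoch(labels[i, ], profile, seeds[i], calib)
    }
  }
  new("EpochedSession", epochs = epochs,
      channelNames = profile@channelNames, sampleRate = EPOCH_FS,
      labels = labels, profile = profile)
}

#' Epoch array accessor
#'
#' @param x An [EpochedSession-class].
#' @return Numeric array trials x channels x samples.
#' @export
epochArray <- function(x) {
  stopifnot(is(x, "EpochedSession"))
  x@epochs
}

#' @describeIn trialLabels labels aligned with the epochs
#' @export
setMethod("trialLabels", "EpochedSession", function(x) x@labels)

#' Write / read an epoched session (raw doubles + JSON sidecar)
#'
#' The sample array is stored as little-endian doubles in trial-major,
#' then channel-major order; the JSON sidecar records dimensions, channel
#' names, sampling rate and per-trial labels.
#'
#' @param x An [EpochedSession-class].
#' @param stem Path stem; writes `<stem>.dat` and `<stem>.json`.
#' @return `writeEpochedSession` returns the stem invisibly;
#'   `readEpochedSession` returns an [EpochedSession-class] (without
#'   profile).
#' @export
writeEpochedSession <- function(x, stem) {
  con <- file(paste0(stem, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(x@epochs), con, size = 8L, endian = "little")
  meta <- list(dim = dim(x@epochs), channelNames = x@channelNames,
               sampleRate = x@sampleRate, labels = x@labels)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname writeEpochedSession
#' @export
readEpochedSession <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  d <- as.integer(meta$dim)
  con <- file(paste0(stem, ".dat"), "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = prod(d), size = 8L, endian = "little")
  new("EpochedSession", epochs = array(v, dim = d),
      channelNames = meta$channelNames, sampleRate = meta$sampleRate,
      labels = as.data.frame(meta$labels), profile = NULL)
}
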