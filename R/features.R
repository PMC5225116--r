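## Band-power feature extraction.
##
## Welch PSD conventions (pinned; any fixed convention cancels in the later
## z-scoring, but one must be chosen for the stage to be testable):
## Hamming-windowed segments of 500 samples (2 s) at 250-sample offsets,
## zero-padded to a 512-point FFT; density scaling 1 / (fs * sum(w^2));
## one-sided spectrum with interior bins doubled (DC and Nyquist not).
## A 750-sample epoch yields exactly two full segments (offsets 0 and 250).

hammingWindow <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
}

#' Welch power spectral density of a single channel
#'
#' @param x Numeric vector of samples.
#' @param fs Sampling rate in Hz (default 250).
#' @param windowLen Segment length in samples (default 500).
#' @param overlap Segment overlap in samples (default 250).
#' @param nfft FFT length (default 512; segments are zero-padded).
#' @return List with `freq` (bin center frequencies, 0..fs/2, spacing
#'   fs/nfft) and `power` (one-sided PSD, power per Hz).
#' @export
#' @examples
#' p <- welchPsd(sin(2 * pi * 10 * (0:749) / 250))
#' p$freq[which.max(p$power)]
welchPsd <- function(x, fs = 250, windowLen = 500L, overlap = 250L,
                     nfft = 512L) {
  n <- length(x)
  if (n < windowLen) {
    stop(sprintf("signal length %d is shorter than one window (%d samples)",
                 n, windowLen), call. = FALSE)
  }
  psd <- welchPsdMatrix(matrix(x, nrow = 1L), fs, windowLen, overlap, nfft)
  list(freq = attr(psd, "freq"), power = psd[1L, ])
}

## Vectorized core: rows of `xm` are channels; returns channels x bins
## matrix with the frequency grid attached.
welchPsdMatrix <- function(xm, fs = 250, windowLen = 500L, overlap = 250L,
                           nfft = 512L) {
  nc <- nrow(xm)
  n <- ncol(xm)
  step <- windowLen - overlap
  stopifnot(step >= 1L, nfft >= windowLen)
  starts <- seq.int(1L, n - windowLen + 1L, by = step)  # full segments only
  w <- hammingWindow(windowLen)
  U <- sum(w^2)
  nbin <- nfft %/% 2L + 1L
  ## stack all (channel, segment) pairs as columns of one padded matrix
  seg <- matrix(0, nfft, nc * length(starts))
  col <- 0L
  for (s in starts) {
    idx <- s:(s + windowLen - 1L)
    seg[seq_len(windowLen), col + seq_len(nc)] <- t(xm[, idx, drop = FALSE]) * w
    col <- col + nc
  }
  F <- stats::mvfft(seg)
  P <- Mod(F[seq_len(nbin), , drop = FALSE])^2 / (fs * U)
  P[2:(nbin - 1L), ] <- 2 * P[2:(nbin - 1L), ]   # one-sided; DC/Nyquist undoubled
  ## average periodograms across segments per channel
  out <- matrix(0, nc, nbin)
  for (k in seq_along(starts)) {
    out <- out + t(P[, (k - 1L) * nc + seq_len(nc), drop = FALSE])
  }
  out <- out / length(starts)
  attr(out, "freq") <- (seq_len(nbin) - 1L) * fs / nfft
  out
}

#' Average PSD into frequency bands
#'
#' A spectral bin belongs to a band when its center frequency lies in the
#' closed interval `[low, high]`; the band value is the mean of its bins'
#' PSD. Bins between the (gapped) band edges belong to no band.
#'
#' @param spectrum Output of [welchPsd()].
#' @param bands Band definitions (see [defaultBands()]).
#' @return Named numeric vector of per-band power values.
#' @export
bandPower <- function(spectrum, bands = defaultBands()) {
  validateBands(bands)
  out <- vapply(seq_len(nrow(bands)), function(b) {
    sel <- spectrum$freq >= bands$low[b] & spectrum$freq <= bands$high[b]
    if (!any(sel)) {
      stop(sprintf("band %s [%g, %g] Hz contains no frequency bins",
                   bands$band[b], bands$low[b], bands$high[b]),
           call. = FALSE)
    }
    mean(spectrum$power[sel])
  }, numeric(1))
  names(out) <- bands$band
  out
}

#' Extract log band-power features from an epoched session
#'
#' Per trial, per channel, per band: the natural logarithm of the Welch
#' band power. Feature order is channel-major with bands in band-table
#' order within channel; names are `<channel>.<band>`. With 32 channels
#' and 6 bands the feature vector has length 192.
#'
#' @param epochedSession An [EpochedSession-class].
#' @param bands Band definitions.
#' @return A [WorkloadFeatures-class] (unnormalized). Nonpositive band
#'   powers (possible only for degenerate all-zero signals) become NA with
#'   a warning.
#' @export
extractFeatures <- function(epochedSession, bands = defaultBands()) {
  validateBands(bands)
  ep <- epochedSession@epochs
  n <- dim(ep)[1]
  chans <- epochedSession@channelNames
  nc <- length(chans)
  nb <- nrow(bands)
  vals <- matrix(NA_real_, nc * nb, max(n, 0L))
  fs <- epochedSession@sampleRate
  for (i in seq_len(n)) {
    xm <- matrix(ep[i, , ], nrow = nc)   # robust to nc == 1
    psd <- welchPsdMatrix(xm, fs = fs)
    freq <- attr(psd, "freq")
    bp <- vapply(seq_len(nb), function(b) {
      sel <- freq >= bands$low[b] & freq <= bands$high[b]
      if (!any(sel)) stop("band with no bins", call. = FALSE)
      rowMeans(psd[, sel, drop = FALSE])
    }, numeric(nc))                     # channels x bands
    vals[, i] <- as.vector(t(bp))       # channel-major, bands inner
  }
  if (any(vals <= 0, na.rm = TRUE)) {
    warning("nonpositive band power encountered; set to NA")
    vals[vals <= 0] <- NA_real_
  }
  vals[!is.na(vals)] <- log(vals[!is.na(vals)])
  grid <- expand.grid(band = bands$band, channel = chans,
                      stringsAsFactors = FALSE)[, c(2, 1)]
  rownames(vals) <- paste0(grid$channel, ".", grid$band)
  labels <- epochedSession@labels
  if (n == 0L) vals <- matrix(numeric(0), nc * nb, 0L,
                              dimnames = list(rownames(vals), NULL))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(logpower = vals),
    rowData = S4Vectors::DataFrame(channel = grid$channel, band = grid$band),
    colData = S4Vectors::DataFrame(labels)
  )
  new("WorkloadFeatures", se)
}

#' @describeIn featureValues trials x features matrix of log band power
#' @export
setMethod("featureValues", "WorkloadFeatures", function(x) {
  t(SummarizedExperiment::assay(x, "logpower"))
})

#' @describeIn trialLabels per-trial labels of a feature container
#' @export
setMethod("trialLabels", "WorkloadFeatures", function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
})

#' Train-set z-scoring
#'
#' `fitNormalizer` computes per-feature mean and SD from training rows
#' only; `applyNormalizer` applies those statistics to any matrix (train
#' or test), so test trials are placed on the training scale. Features
#' with zero training SD are flagged and set to 0 everywhere, with a
#' message.
#'
#' @param train Numeric matrix of training rows (trials x features).
#' @return A [NormalizerStats-class].
#' @export
fitNormalizer <- function(train) {
  if (!is.matrix(train) || nrow(train) < 2L) {
    stop("need a matrix with at least 2 training rows", call. = FALSE)
  }
  mu <- colMeans(train)
  s <- apply(train, 2L, stats::sd)
  constant <- s == 0
  if (any(constant)) {
    message(sum(constant), " feature(s) constant on the training set; ",
            "they will be set to 0")
  }
  new("NormalizerStats", mean = mu, sd = s, constant = constant)
}

#' @rdname fitNormalizer
#' @param x Numeric matrix (trials x features) to normalize.
#' @param stats A [NormalizerStats-class] from `fitNormalizer`.
#' @return `applyNormalizer` returns the normalized matrix.
#' @export
applyNormalizer <- function(x, stats) {
  stopifnot(is(stats, "NormalizerStats"), ncol(x) == length(stats@mean))
  s <- ifelse(stats@constant, 1, stats@sd)
  out <- sweep(sweep(x, 2L, stats@mean, `-`), 2L, s, `/`)
  out[, stats@constant] <- 0
  out
}

#' Write / read a feature matrix as CSV
#'
#' Header: `participant,mode,level,block,trial,subjective,<CH>.<band>...`;
#' feature values are written with 17 significant digits so the matrix
#' round-trips bit-exactly through the text format.
#'
#' @param features A [WorkloadFeatures-class].
#' @param path File path.
#' @return `writeFeaturesCsv` returns `path` invisibly; `readFeaturesCsv`
#'   returns a [WorkloadFeatures-class].
#' @export
writeFeaturesCsv <- function(features, path) {
  lab <- trialLabels(features)
  vals <- featureValues(features)
  meta <- data.frame(
    participant = lab$participant, mode = lab$mode, level = lab$level,
    block = lab$block, trial = lab$trial, subjective = lab$rating,
    stringsAsFactors = FALSE)
  txt <- apply(vals, 2L, function(col) sprintf("%.17g", col))
  if (is.null(dim(txt))) txt <- matrix(txt, nrow = nrow(vals))
  colnames(txt) <- colnames(vals)
  write.csv(cbind(meta, as.data.frame(txt, optional = TRUE)), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeaturesCsv
#' @export
readFeaturesCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  metaCols <- c("participant", "mode", "level", "block", "trial", "subjective")
  featCols <- setdiff(names(df), metaCols)
  vals <- t(as.matrix(df[, featCols, drop = FALSE]))
  mode(vals) <- "double"
  parts <- strsplit(featCols, ".", fixed = TRUE)
  labels <- data.frame(
    participant = df$participant, mode = df$mode, level = df$level,
    block = df$block, trial = df$trial, rating = df$subjective,
    stringsAsFactors = FALSE)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(logpower = vals),
    rowData = S4Vectors::DataFrame(
      channel = vapply(parts, `[`, character(1), 1L),
      band = vapply(parts, `[`, character(1), 2L)),
    colData = S4Vectors::DataFrame(labels))
  new("WorkloadFeatures", se)
}
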