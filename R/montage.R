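#' Default 32-channel EEG montage
#'
#' Channel names for a 32-electrode active-electrode laboratory cap
#' (10-20/10-10 positions, FCz reference not recorded). This is the default
#' montage of the synthetic-EEG generator and the reference frame for the
#' named electrode subsets in [montageSubsets()]. Fully overridable: any
#' character vector of channel names may be used throughout the package.
#'
#' @return Character vector of 32 channel names.
#' @export
#' @examples
#' length(actiCapMontage())
actiCapMontage <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6",
    "T7", "C3", "Cz", "C4", "T8",
    "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
    "P7", "P3", "Pz", "P4", "P8",
    "POz", "O1", "Oz", "O2", "PO10")
}

#' Named electrode-site subsets of the default montage
#'
#' Channel subsets emulating reduced montages: a 9-channel rapid-deployment
#' headset concentrated on midline sites (Fz, Cz, POz), a 16-channel consumer
#' headset concentrated on lateral sites near the head's equator (F7, F8, P3,
#' P4, P7, P8, ...), and single-region parietal and occipital subsets. With
#' six frequency bands these give 54, 96, 54 and 30 features respectively.
#' The exact channel lists are package defaults and can be replaced by any
#' subset of the montage in use.
#'
#' @return Named list of character vectors of channel names.
#' @seealso [montageSubsetEval()]
#' @export
#' @examples
#' vapply(montageSubsets(), length, integer(1))
montageSubsets <- function() {
  list(
    balert    = c("F3", "F4", "C3", "C4", "P3", "P4", "Fz", "Cz", "POz"),
    emotiv    = c("Fp1", "Fp2", "F7", "F3", "F4", "F8", "FC5", "FC6",
                  "T7", "T8", "P7", "P3", "P4", "P8", "O1", "O2"),
    parietal  = c("CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8"),
    occipital = c("POz", "O1", "Oz", "O2", "PO10")
  )
}

#' Canonical EEG frequency-band definitions
#'
#' The six bands used for band-power feature extraction: delta 1-3 Hz,
#' theta 4-7 Hz, low alpha 8-10 Hz, high alpha 11-12 Hz, beta 13-25 Hz,
#' gamma 26-40 Hz. Band membership of a spectral bin is decided by its
#' center frequency lying in the closed interval `[low, high]`; the printed
#' band edges are gapped, and bins falling between bands belong to none.
#'
#' @return A data.frame with columns `band`, `low`, `high` (Hz).
#' @export
#' @examples
#' defaultBands()
defaultBands <- function() {
  data.frame(
    band = c("delta", "theta", "lowalpha", "highalpha", "beta", "gamma"),
    low  = c(1, 4, 8, 11, 13, 26),
    high = c(3, 7, 10, 12, 25, 40),
    stringsAsFactors = FALSE
  )
}

validateBands <- function(bands) {
  stopifnot(is.data.frame(bands),
            all(c("band", "low", "high") %in% names(bands)))
  if (any(bands$low > bands$high)) {
    stop("band definitions must satisfy low <= high", call. = FALSE)
  }
  o <- order(bands$low)
  b <- bands[o, ]
  if (nrow(b) > 1L && any(b$low[-1L] <= b$high[-nrow(b)])) {
    stop("band definitions must be non-overlapping", call. = FALSE)
  }
  bands
}
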