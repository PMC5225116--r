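#' @importFrom methods new validObject is slot
#' @importFrom stats fft mvfft rnorm runif var cov sd cor optim predict setNames
#' @importFrom utils head tail write.csv read.csv
#' @importFrom withr with_seed
#' @importFrom MASS ginv
#' @importFrom jsonlite write_json read_json
#' @importFrom tools md5sum
#' @importFrom S4Vectors DataFrame
NULL

TASK_MODES <- c("Auditory", "Numeric", "Spatial")
N_STIMULI <- 8L
FORCED_MATCH_PROB <- 1 / 8

#' Derive a fixed number of child seeds from one master seed
#'
#' All stochastic entry points in the package accept a single integer seed;
#' multi-stage operations split it into independent per-stage seeds with this
#' helper so that no function touches the global RNG state outside a
#' [withr::with_seed()] scope.
#'
#' @param seed Integer master seed.
#' @param n Number of child seeds to derive.
#' @return Integer vector of length `n`, each a valid seed below 2^31.
#' @export
#' @examples
#' spawnSeeds(1L, 3L)
spawnSeeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}

## population variance (divide by n); pinned so that the constant-mean
## predictor has standardized error exactly 1
popVar <- function(x) mean((x - mean(x))^2)

assertScalarIn <- function(x, choices, what) {
  if (length(x) != 1L || !(x %in% choices)) {
    stop(sprintf("%s must be one of: %s", what,
                 paste(choices, collapse = ", ")), call. = FALSE)
  }
  x
}

## md5 of an R object via its serialization, for stamping pipeline outputs
objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
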