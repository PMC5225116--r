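## Linear baseline, activation patterns and per-feature ANOVA ranking.

#' Fit the multiple linear regression baseline
#'
#' One linear term per feature plus a constant term, fit by ordinary least
#' squares. When the design is rank deficient (including more features
#' than rows) the minimum-norm solution is returned with a warning.
#'
#' @param X Numeric matrix, trials x features.
#' @param y Numeric targets.
#' @return An [MLRModel-class].
#' @export
fitMlr <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("no rows to fit", call. = FALSE)
  stopifnot(length(y) == nrow(X))
  D <- cbind(1, X)
  qd <- qr(D)
  if (qd$rank < ncol(D)) {
    warning("rank-deficient design; returning the minimum-norm solution")
    beta <- as.numeric(MASS::ginv(D) %*% y)
  } else {
    beta <- as.numeric(qr.coef(qd, y))
  }
  fn <- colnames(X)
  if (is.null(fn)) fn <- paste0("f", seq_len(ncol(X)))
  new("MLRModel", weights = beta[-1L], intercept = beta[1L],
      featureNames = fn)
}

#' @describeIn fitMlr predictions from the linear baseline (returned as a
#'   [PredictionSet-class] with NA variances)
#' @param object An [MLRModel-class].
#' @param newdata Test inputs.
#' @param truth Optional true labels.
#' @param ... Ignored.
#' @export
setMethod("predict", "MLRModel", function(object, newdata, truth = NULL, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object@weights)) {
    stop("feature dimension mismatch", call. = FALSE)
  }
  mu <- as.numeric(newdata %*% object@weights + object@intercept)
  n <- length(mu)
  ps <- new("PredictionSet", truth = rep(NA_real_, n), mean = mu,
            varLatent = rep(0, n), varObs = rep(0, n),
            fold = rep(NA_integer_, n))
  if (!is.null(truth)) ps@truth <- as.numeric(truth)
  ps
})

#' Haufe-style activation pattern of a linear decoder
#'
#' Transforms regression weights W into interpretable activations
#' `A = Sigma_x W / var(s)`, where `Sigma_x` is the feature covariance of
#' the supplied data and `s` is the latent factor. By default the latent
#' factor is the model's fitted predictions on that data; set
#' `latent = "labels"` to use the labels themselves instead (both readings
#' of the latent factor are supported; they coincide up to scale for a
#' least-squares fit).
#'
#' @param model An [MLRModel-class].
#' @param X The data whose covariance enters the transformation.
#' @param y Labels; required when `latent = "labels"`.
#' @param latent `"fitted"` (default) or `"labels"`.
#' @return Named numeric vector of per-feature activations.
#' @export
activationPattern <- function(model, X, y = NULL,
                              latent = c("fitted", "labels")) {
  latent <- match.arg(latent)
  X <- as.matrix(X)
  s <- if (latent == "fitted") {
    as.numeric(X %*% model@weights + model@intercept)
  } else {
    if (is.null(y)) stop("y required for latent = 'labels'", call. = FALSE)
    as.numeric(y)
  }
  vs <- stats::var(s)
  if (!is.finite(vs) || vs == 0) {
    stop("latent factor has zero variance", call. = FALSE)
  }
  A <- as.numeric(stats::cov(X) %*% model@weights) / vs
  stats::setNames(A, model@featureNames)
}

#' Per-feature one-way ANOVA F for task level
#'
#' Classical between/within mean-square ratio of each feature across the
#' level groups (N = 1, 2, 3), vectorized over features. Larger F ranks as
#' more relevant (rank 1 = largest F; ties broken by feature index). If
#' any group has fewer than 2 members the F values are undefined and
#' returned as NA.
#'
#' @param X Numeric matrix, trials x features.
#' @param groups Grouping vector (task level per trial).
#' @return data.frame with columns `feature`, `F`, `rank`.
#' @export
anovaFPerFeature <- function(X, groups) {
  X <- as.matrix(X)
  stopifnot(length(groups) == nrow(X))
  g <- as.factor(groups)
  counts <- table(g)
  fn <- colnames(X)
  if (is.null(fn)) fn <- paste0("f", seq_len(ncol(X)))
  if (nlevels(g) < 2L || any(counts < 2L)) {
    warning("need >= 2 groups with >= 2 members each; F set to NA")
    return(data.frame(feature = fn, F = NA_real_,
                      rank = NA_integer_, stringsAsFactors = FALSE))
  }
  n <- nrow(X)
  k <- nlevels(g)
  grand <- colMeans(X)
  gm <- rowsum(X, g) / as.vector(counts)          # group means, k x d
  ssb <- colSums(as.vector(counts) * sweep(gm, 2L, grand, `-`)^2)
  sst <- colSums(sweep(X, 2L, grand, `-`)^2)
  ssw <- sst - ssb
  Fv <- (ssb / (k - 1)) / (ssw / (n - k))
  ord <- order(-Fv, seq_along(Fv))
  rk <- integer(length(Fv))
  rk[ord] <- seq_along(Fv)
  data.frame(feature = fn, F = Fv, rank = rk, stringsAsFactors = FALSE)
}

#' Rank features by ARD length scale or ANOVA F
#'
#' Unified ranking interface for feature-subset selection: `"ard"` ranks
#' by ascending trained GP length scale, `"anova"` by descending
#' one-way-ANOVA F computed on supplied training data.
#'
#' @param method `"ard"` or `"anova"`.
#' @param model Trained [GPModel-class] (required for `"ard"`).
#' @param X,groups Training data and level labels (required for
#'   `"anova"`).
#' @return data.frame with columns `feature`, the ranking score, and
#'   `rank` (1 = most relevant).
#' @export
rankFeatures <- function(method = c("ard", "anova"), model = NULL,
                         X = NULL, groups = NULL) {
  method <- match.arg(method)
  if (method == "ard") {
    if (is.null(model)) stop("model required for method 'ard'", call. = FALSE)
    lengthScales(model)
  } else {
    if (is.null(X) || is.null(groups)) {
      stop("X and groups required for method 'anova'", call. = FALSE)
    }
    anovaFPerFeature(X, groups)
  }
}
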