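## Exact Gaussian process regression with squared-exponential ARD
## covariance, constant zero mean and Gaussian likelihood.
##
## k(xp, xq) = sf2 * exp(-1/2 (xp-xq)' diag(l)^-2 (xp-xq))
##
## Hyperparameters (one length scale per feature, signal variance sf2,
## noise variance sn2) are optimized on the log scale by minimizing the
## negative log marginal likelihood
##   1/2 y'(K+sn2 I)^-1 y + 1/2 log det(K+sn2 I) + n/2 log 2pi
## with analytic gradients, using a deterministic quasi-Newton optimizer
## (L-BFGS-B) capped at a fixed evaluation budget. All linear algebra goes
## through a Cholesky factorization with an escalating-jitter fallback;
## explicit matrix inversion is never formed for prediction.

GPR_JITTER_BASE <- 1e-10
GPR_JITTER_GROWTH <- 10
GPR_JITTER_RETRIES <- 3L

#' Squared-exponential ARD covariance between two feature vectors
#'
#' @param xp,xq Numeric feature vectors of equal length.
#' @param lengthScales Positive vector, one per feature.
#' @param signalVar Signal variance sf2 (> 0).
#' @return Covariance scalar in (0, signalVar].
#' @export
#' @examples
#' seArdKernel(0, 1, lengthScales = 1)   # exp(-0.5)
seArdKernel <- function(xp, xq, lengthScales, signalVar = 1) {
  if (length(xp) != length(xq) || length(lengthScales) != length(xp)) {
    stop("dimension mismatch between inputs and length scales",
         call. = FALSE)
  }
  d <- (xp - xq) / lengthScales
  signalVar * exp(-0.5 * sum(d * d))
}

#' Covariance (Gram) matrix between two sets of inputs
#'
#' @param X1,X2 Numeric matrices (rows = points) with a shared feature
#'   dimension.
#' @inheritParams seArdKernel
#' @return Matrix of size nrow(X1) x nrow(X2); for `X1 == X2` it is
#'   symmetric positive semidefinite with diagonal `signalVar`.
#' @export
gramMatrix <- function(X1, X2, lengthScales, signalVar = 1) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (ncol(X1) != ncol(X2) || ncol(X1) != length(lengthScales)) {
    stop("dimension mismatch between inputs and length scales",
         call. = FALSE)
  }
  A <- sweep(X1, 2L, lengthScales, `/`)
  B <- sweep(X2, 2L, lengthScales, `/`)
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0   # round-off
  signalVar * exp(-0.5 * d2)
}

## Cholesky of Ky with escalating jitter; returns list(U, jitter).
cholJitter <- function(Ky) {
  base <- GPR_JITTER_BASE * mean(diag(Ky))
  jit <- 0
  for (try in 0:GPR_JITTER_RETRIES) {
    U <- tryCatch(chol(Ky + diag(jit, nrow(Ky))), error = function(e) NULL)
    if (!is.null(U)) return(list(U = U, jitter = jit))
    jit <- if (jit == 0) base else jit * GPR_JITTER_GROWTH
  }
  stop("Cholesky factorization failed after jitter escalation",
       call. = FALSE)
}

## unpack c(log l_1..d, log sf2, log sn2)
unpackTheta <- function(logTheta, d) {
  list(ls = exp(logTheta[seq_len(d)]),
       sf2 = exp(logTheta[d + 1L]),
       sn2 = exp(logTheta[d + 2L]))
}

#' Negative log marginal likelihood and its gradient
#'
#' Value and gradient with respect to the log hyperparameters
#' `c(log lengthScales, log signalVar, log noiseVar)` of the zero-mean GP
#' marginal likelihood.
#'
#' @param logTheta Numeric vector of log hyperparameters (length
#'   `ncol(X) + 2`).
#' @param X Training inputs (trials x features).
#' @param y Training targets.
#' @return List with `value`, `grad` and the `jitter` used (0 if none).
#' @export
negLogMarginalLikelihood <- function(logTheta, X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- ncol(X)
  stopifnot(length(y) == n, n >= 1L, length(logTheta) == d + 2L)
  th <- unpackTheta(logTheta, d)
  K <- gramMatrix(X, X, th$ls, th$sf2)
  fac <- cholJitter(K + diag(th$sn2, n))
  U <- fac$U
  alpha <- backsolve(U, backsolve(U, y, transpose = TRUE))
  value <- 0.5 * sum(y * alpha) + sum(log(diag(U))) + 0.5 * n * log(2 * pi)

  Kinv <- chol2inv(U)
  W <- Kinv - tcrossprod(alpha)          # d(NLML)/dKy = W / 2
  M <- W * K
  ## quadratic forms sum_ij M_ij (x_id - x_jd)^2, all dimensions at once
  q <- 2 * (as.vector(crossprod(X^2, rowSums(M))) -
            colSums(X * (M %*% X)))
  grad <- c(0.5 * q / th$ls^2,           # wrt log l_d
            0.5 * sum(M),                # wrt log sf2
            0.5 * th$sn2 * sum(diag(W))) # wrt log sn2
  list(value = value, grad = grad, jitter = fac$jitter)
}

#' Train a GP regression model
#'
#' Starts from the default hyperparameters (every length scale 10, signal
#' variance 1, noise variance 1) and minimizes the negative log marginal
#' likelihood over the log hyperparameters with L-BFGS-B, capped at
#' `maxEvals` optimizer iterations (each iteration makes one
#' function-and-gradient evaluation plus any line-search evaluations).
#' The returned model never has a higher objective than the
#' initialization.
#'
#' @param X Training inputs (trials x features), typically z-scored.
#' @param y Training targets (task level N or subjective rating).
#' @param lengthScale Initial length scale(s); scalar recycled per feature
#'   (default 10).
#' @param signalVar,noiseVar Initial variances (default 1).
#' @param maxEvals Optimization budget (default 100).
#' @param optimize Set FALSE to keep the initial hyperparameters.
#' @return A [GPModel-class].
#' @export
trainGpr <- function(X, y, lengthScale = 10, signalVar = 1, noiseVar = 1,
                     maxEvals = 100L, optimize = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  stopifnot(length(y) == n)
  ls0 <- rep_len(lengthScale, d)
  stopifnot(all(ls0 > 0), signalVar > 0, noiseVar > 0)
  theta0 <- c(log(ls0), log(signalVar), log(noiseVar))

  path <- numeric(0)
  cache <- new.env(parent = emptyenv())
  evalAt <- function(par) {
    key <- paste(format(par, digits = 17), collapse = ",")
    if (!identical(cache$key, key)) {
      cache$key <- key
      cache$res <- negLogMarginalLikelihood(par, X, y)
      path[length(path) + 1L] <<- cache$res$value
    }
    cache$res
  }
  f0 <- evalAt(theta0)
  if (!is.finite(f0$value)) {
    stop("objective not finite at initialization", call. = FALSE)
  }

  theta <- theta0
  if (optimize && maxEvals > 0L) {
    fit <- tryCatch(
      stats::optim(theta0,
                   fn = function(p) evalAt(p)$value,
                   gr = function(p) evalAt(p)$grad,
                   method = "L-BFGS-B",
                   control = list(maxit = as.integer(maxEvals))),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) && fit$value <= f0$value) {
      theta <- fit$par
    }
  }

  th <- unpackTheta(theta, d)
  K <- gramMatrix(X, X, th$ls, th$sf2)
  fac <- cholJitter(K + diag(th$sn2, n))
  alpha <- backsolve(fac$U, backsolve(fac$U, y, transpose = TRUE))
  final <- negLogMarginalLikelihood(theta, X, y)$value
  fn <- colnames(X)
  if (is.null(fn)) fn <- paste0("f", seq_len(d))
  new("GPModel", X = X, y = as.numeric(y), logTheta = theta,
      featureNames = fn, U = fac$U, alpha = as.numeric(alpha),
      jitter = fac$jitter, nlmlPath = c(f0$value, path), nlml = final)
}

#' @describeIn hyperparams natural-scale hyperparameters
#' @export
setMethod("hyperparams", "GPModel", function(model) {
  d <- ncol(model@X)
  th <- unpackTheta(model@logTheta, d)
  list(lengthScales = stats::setNames(th$ls, model@featureNames),
       signalVar = th$sf2, noiseVar = th$sn2)
})

#' @describeIn lengthScales ARD relevance ranking of a trained model
#' @export
setMethod("lengthScales", "GPModel", function(model) {
  th <- hyperparams(model)
  ls <- th$lengthScales
  ord <- order(ls, seq_along(ls))
  rk <- integer(length(ls))
  rk[ord] <- seq_along(ls)
  data.frame(feature = model@featureNames, lengthScale = unname(ls),
             rank = rk, stringsAsFactors = FALSE)
})

## shared posterior computation given a factorization over (possibly
## subsetted) training inputs
gpPosterior <- function(Xtrain, y, U, alpha, ls, sf2, sn2, Xstar,
                        includeNoise) {
  Ks <- gramMatrix(Xstar, Xtrain, ls, sf2)         # m x n
  mu <- as.numeric(Ks %*% alpha)
  V <- backsolve(U, t(Ks), transpose = TRUE)       # n x m
  varLatent <- sf2 - colSums(V^2)
  neg <- varLatent < 0
  if (any(neg)) {
    message(sum(neg), " negative predictive variance(s) clamped to 0")
    varLatent[neg] <- 0
  }
  new("PredictionSet", truth = rep(NA_real_, length(mu)), mean = mu,
      varLatent = varLatent, varObs = varLatent + sn2,
      fold = rep(NA_integer_, length(mu)))
}

#' Posterior prediction from a trained GP model
#'
#' Computes the posterior mean `K(X*,X) [K(X,X)+sn2 I]^-1 y` and the
#' per-point posterior variance
#' `diag(K(X*,X*) - K(X*,X)[K(X,X)+sn2 I]^-1 K(X,X*))` through the cached
#' Cholesky factorization. `varObs` additionally includes the noise
#' variance and is the quantity behind plotted +/- 2 sigma bands.
#'
#' @param object A trained [GPModel-class].
#' @param newdata Matrix of test inputs (trials x features), on the same
#'   normalized scale as the training inputs.
#' @param truth Optional numeric vector of true labels to attach.
#' @param ... Ignored.
#' @return A [PredictionSet-class].
#' @export
setMethod("predict", "GPModel", function(object, newdata, truth = NULL, ...) {
  newdata <- as.matrix(newdata)
  d <- ncol(object@X)
  if (ncol(newdata) != d) {
    stop("feature dimension mismatch", call. = FALSE)
  }
  th <- unpackTheta(object@logTheta, d)
  ps <- gpPosterior(object@X, object@y, object@U, object@alpha,
                    th$ls, th$sf2, th$sn2, newdata, TRUE)
  if (!is.null(truth)) ps@truth <- as.numeric(truth)
  ps
})

#' Predict using only a subset of features
#'
#' Evaluates the trained model's kernel over the retained dimensions only,
#' restricting the training inputs to the same columns and keeping the
#' trained length scales for those dimensions. By default the
#' hyperparameters are NOT refit: the reduced model reuses what was
#' learned on the full feature set, which is the regime of interest when a
#' full-montage calibration is deployed on a reduced montage. Set
#' `refit = TRUE` to re-optimize on the retained columns instead.
#'
#' @param model A trained [GPModel-class].
#' @param Xstar Test inputs with either all original columns (they are
#'   subset internally) or exactly the retained columns.
#' @param retained Integer or character vector of feature indices/names;
#'   must be nonempty.
#' @param truth Optional true labels.
#' @param refit Re-optimize hyperparameters on the retained columns
#'   (default FALSE).
#' @param maxEvals Budget for the refit, if requested.
#' @return A [PredictionSet-class].
#' @export
predictWithFeatureSubset <- function(model, Xstar, retained, truth = NULL,
                                     refit = FALSE, maxEvals = 100L) {
  d <- ncol(model@X)
  if (is.character(retained)) {
    retained <- match(retained, model@featureNames)
  }
  retained <- as.integer(retained)
  if (length(retained) == 0L || anyNA(retained) ||
      any(retained < 1L | retained > d)) {
    stop("retained must be a nonempty subset of the model's features",
         call. = FALSE)
  }
  Xstar <- as.matrix(Xstar)
  if (ncol(Xstar) == d) {
    Xstar <- Xstar[, retained, drop = FALSE]
  } else if (ncol(Xstar) != length(retained)) {
    stop("Xstar must have all original columns or the retained columns",
         call. = FALSE)
  }
  th <- unpackTheta(model@logTheta, d)
  Xsub <- model@X[, retained, drop = FALSE]
  if (refit) {
    sub <- trainGpr(Xsub, model@y, lengthScale = th$ls[retained],
                    signalVar = th$sf2, noiseVar = th$sn2,
                    maxEvals = maxEvals)
    ps <- predict(sub, Xstar)
  } else {
    K <- gramMatrix(Xsub, Xsub, th$ls[retained], th$sf2)
    fac <- cholJitter(K + diag(th$sn2, nrow(Xsub)))
    alpha <- backsolve(fac$U, backsolve(fac$U, model@y, transpose = TRUE))
    ps <- gpPosterior(Xsub, model@y, fac$U, as.numeric(alpha),
                      th$ls[retained], th$sf2, th$sn2, Xstar, TRUE)
  }
  if (!is.null(truth)) ps@truth <- as.numeric(truth)
  ps
}

#' Serialize / restore a GP model as structured text
#'
#' Writes hyperparameters, feature names and the training data to a JSON
#' file (schema version 1). Arrays are stored at full double precision.
#'
#' @param model A [GPModel-class].
#' @param path File path.
#' @return `writeGpModel` returns `path` invisibly; `readGpModel` returns
#'   the reconstructed [GPModel-class] (factorization recomputed).
#' @export
writeGpModel <- function(model, path) {
  obj <- list(schema = 1L, featureNames = model@featureNames,
              logTheta = model@logTheta, y = model@y,
              X = apply(model@X, 1L, identity, simplify = FALSE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeGpModel
#' @export
readGpModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  X <- if (is.list(obj$X)) do.call(rbind, obj$X) else as.matrix(obj$X)
  colnames(X) <- obj$featureNames
  d <- ncol(X)
  th <- unpackTheta(obj$logTheta, d)
  fac <- cholJitter(gramMatrix(X, X, th$ls, th$sf2) +
                    diag(th$sn2, nrow(X)))
  alpha <- backsolve(fac$U, backsolve(fac$U, obj$y, transpose = TRUE))
  final <- negLogMarginalLikelihood(obj$logTheta, X, obj$y)$value
  new("GPModel", X = X, y = obj$y, logTheta = obj$logTheta,
      featureNames = obj$featureNames, U = fac$U,
      alpha = as.numeric(alpha), jitter = fac$jitter,
      nlmlPath = final, nlml = final)
}
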