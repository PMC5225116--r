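test_that("the SE-ARD kernel evaluates its closed form", {
  expect_equal(seArdKernel(c(1, 2), c(1, 2), c(1, 1), signalVar = 2.5), 2.5)
  expect_equal(seArdKernel(0, 1, lengthScales = 1), exp(-0.5))
  # doubling both the length scale and the separation leaves it unchanged
  expect_equal(seArdKernel(0, 2, lengthScales = 2), seArdKernel(0, 1, 1))
  expect_error(seArdKernel(c(1, 2), c(1, 2, 3), c(1, 1)), "dimension")
})

test_that("the Gram matrix matches an elementwise double loop", {
  set.seed(1)
  X1 <- matrix(rnorm(15), 5, 3)
  X2 <- matrix(rnorm(12), 4, 3)
  ls <- c(0.7, 1.3, 2.1)
  K <- gramMatrix(X1, X2, ls, signalVar = 1.8)
  brute <- outer(seq_len(5), seq_len(4), Vectorize(function(i, j)
    seArdKernel(X1[i, ], X2[j, ], ls, 1.8)))
  expect_equal(K, brute, tolerance = 1e-12)
  Ks <- gramMatrix(X1, X1, ls, 1.8)
  expect_equal(Ks, t(Ks))
  expect_equal(unname(diag(Ks)), rep(1.8, 5))
  expect_true(all(eigen(Ks, symmetric = TRUE, only.values = TRUE)$values > -1e-10))
  same <- matrix(1, 3, 2)
  expect_true(all(gramMatrix(same, same, c(1, 1), 2) == 2))
})

test_that("the marginal likelihood matches its scalar closed forms", {
  # n = 1: NLML = y^2 / (2 (sf2+sn2)) + log(sf2+sn2)/2 + log(2 pi)/2
  v0 <- negLogMarginalLikelihood(c(log(1), log(0.5), log(0.5)),
                                 matrix(0, 1, 1), 0)$value
  expect_equal(v0, 0.5 * log(2 * pi))
  y0 <- 1.7; sf2 <- 0.9; sn2 <- 0.4
  v1 <- negLogMarginalLikelihood(c(log(2), log(sf2), log(sn2)),
                                 matrix(3.2, 1, 1), y0)$value
  expect_equal(v1, 0.5 * y0^2 / (sf2 + sn2) + 0.5 * log(sf2 + sn2) +
                 0.5 * log(2 * pi))
})

test_that("analytic NLML gradients match central finite differences", {
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(rnorm(24), 8, 3)
    y <- rnorm(8)
    theta <- rnorm(5, sd = 0.4)
    g <- negLogMarginalLikelihood(theta, X, y)$grad
    fd <- vapply(seq_along(theta), function(j) {
      h <- 1e-6
      tp <- theta; tp[j] <- tp[j] + h
      tm <- theta; tm[j] <- tm[j] - h
      (negLogMarginalLikelihood(tp, X, y)$value -
         negLogMarginalLikelihood(tm, X, y)$value) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-6)), 1e-5)
  }
})

test_that("training reduces the objective deterministically", {
  set.seed(4)
  X <- matrix(rnorm(60), 30, 2)
  y <- sin(X[, 1]) + rnorm(30, sd = 0.1)
  m1 <- trainGpr(X, y, maxEvals = 50L)
  m2 <- trainGpr(X, y, maxEvals = 50L)
  expect_identical(m1@logTheta, m2@logTheta)
  expect_lte(m1@nlml, m1@nlmlPath[1])
  # all-zero targets: objective cannot increase, predictions stay at 0
  m0 <- trainGpr(X, rep(0, 30), maxEvals = 20L)
  expect_lte(m0@nlml, m0@nlmlPath[1])
  expect_equal(predict(m0, X)@mean, rep(0, 30), tolerance = 1e-10)
  expect_error(trainGpr(X, y, lengthScale = -1), "positive|> 0")
})

test_that("posterior prediction reproduces its scalar closed form", {
  # single training point (x0, y0 = 1), sf2 = sn2 = 1, prediction at x0:
  # mean = 1 * (1 + 1)^-1 * 1 = 0.5; latent var = 1 - 1/(1+1) = 0.5
  m <- trainGpr(matrix(0, 1, 1), 1, lengthScale = 1, optimize = FALSE)
  ps <- predict(m, matrix(0, 1, 1))
  expect_equal(ps@mean, 0.5)
  expect_equal(ps@varLatent, 0.5)
  expect_equal(ps@varObs, 1.5)
  # far from the data the prior is recovered
  far <- predict(m, matrix(100, 1, 1))
  expect_equal(far@mean, 0, tolerance = 1e-12)
  expect_equal(far@varLatent, 1, tolerance = 1e-12)
})

test_that("the noise-free limit interpolates the training targets", {
  set.seed(5)
  X <- matrix(rnorm(20), 10, 2)
  y <- rnorm(10)
  m <- trainGpr(X, y, lengthScale = 1, noiseVar = 1e-10, optimize = FALSE)
  expect_equal(predict(m, X)@mean, y, tolerance = 1e-5)
})

test_that("factorized posterior equals dense brute-force evaluation", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(10:50, 1); d <- sample(2:5, 1); mStar <- 7
    X <- matrix(rnorm(n * d), n, d)
    y <- rnorm(n)
    Xs <- matrix(rnorm(mStar * d), mStar, d)
    ls <- runif(d, 0.5, 3); sf2 <- runif(1, 0.5, 2); sn2 <- runif(1, 0.1, 1)
    m <- trainGpr(X, y, lengthScale = ls, signalVar = sf2, noiseVar = sn2,
                  optimize = FALSE)
    ps <- predict(m, Xs)
    Ky <- gramMatrix(X, X, ls, sf2) + diag(sn2, n)
    Ks <- gramMatrix(Xs, X, ls, sf2)
    mu <- as.numeric(Ks %*% solve(Ky, y))
    V <- diag(gramMatrix(Xs, Xs, ls, sf2) - Ks %*% solve(Ky, t(Ks)))
    expect_equal(ps@mean, mu, tolerance = 1e-8)
    expect_equal(ps@varLatent, V, tolerance = 1e-8)
    expect_true(all(ps@varLatent <= sf2 + 1e-10))
  }
})

test_that("feature-subset prediction restricts the kernel correctly", {
  set.seed(6)
  X <- matrix(rnorm(200), 50, 4)
  y <- X[, 1] + rnorm(50, sd = 0.2)
  Xs <- matrix(rnorm(40), 10, 4)
  m <- trainGpr(X, y, maxEvals = 50L)
  full <- predictWithFeatureSubset(m, Xs, 1:4)
  expect_equal(full@mean, predict(m, Xs)@mean, tolerance = 1e-12)
  expect_equal(full@varLatent, predict(m, Xs)@varLatent, tolerance = 1e-12)
  # single retained feature agrees with a fresh 1-D computation
  h <- hyperparams(m)
  one <- predictWithFeatureSubset(m, Xs, 1L)
  Ky <- gramMatrix(X[, 1, drop = FALSE], X[, 1, drop = FALSE],
                   h$lengthScales[1], h$signalVar) + diag(h$noiseVar, 50)
  Ks <- gramMatrix(Xs[, 1, drop = FALSE], X[, 1, drop = FALSE],
                   h$lengthScales[1], h$signalVar)
  expect_equal(one@mean, as.numeric(Ks %*% solve(Ky, y)), tolerance = 1e-8)
  expect_error(predictWithFeatureSubset(m, Xs, integer(0)), "nonempty")
  expect_error(predictWithFeatureSubset(m, Xs, 9L), "subset")
})

test_that("length-scale ranking is ascending with index tie-breaks", {
  m <- trainGpr(matrix(rnorm(40), 10, 4), rnorm(10), optimize = FALSE)
  r <- lengthScales(m)   # all length scales equal 10
  expect_equal(r$rank, 1:4)
  expect_equal(r$lengthScale, rep(10, 4))
})

test_that("GP models round-trip through the text serialization", {
  set.seed(7)
  X <- matrix(rnorm(30), 10, 3)
  y <- rnorm(10)
  m <- trainGpr(X, y, maxEvals = 25L)
  path <- withr::local_tempfile(fileext = ".json")
  writeGpModel(m, path)
  back <- readGpModel(path)
  expect_equal(back@logTheta, m@logTheta)
  Xs <- matrix(rnorm(9), 3, 3)
  expect_equal(predict(back, Xs)@mean, predict(m, Xs)@mean, tolerance = 1e-10)
})
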