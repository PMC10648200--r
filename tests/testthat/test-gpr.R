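test_that("squared-exponential kernel matches its closed form", {
  f1 <- rnorm(12)
  expect_equal(seKernel(f1, f1, 2, 1.5), 4)
  # distance sigmaL * sqrt(2) gives sigmaF^2 / e
  f2 <- f1 + c(1.5 * sqrt(2), rep(0, 11))
  expect_equal(seKernel(f1, f2, 2, 1.5), 4 * exp(-1))
  # monotone decay towards zero
  d <- seq(0.1, 20, by = 0.5)
  vals <- vapply(d, function(dd)
    seKernel(0, dd, 1, 1), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[length(vals)], 1e-12)
  expect_error(seKernel(f1, f1, -1, 1))
})

test_that("GLS basis coefficient reduces to means and hand cases", {
  F1 <- rnorm(8)
  expect_equal(betaHat(diag(8), F1), mean(F1))
  # constant response passes through any SPD weighting
  set.seed(4)
  A <- crossprod(matrix(rnorm(64), 8))
  expect_equal(betaHat(A + diag(8), rep(3.3, 8)), 3.3, tolerance = 1e-10)
  # 2x2 hand computation
  expect_equal(betaHat(diag(c(2, 2)), c(4, 8)), 6)
})

test_that("log marginal likelihood matches a dense-inverse oracle", {
  # n = 1 closed form with the quadratic term vanishing
  expect_equal(logMarginalLikelihood(1, 1, 1.5, matrix(0, 1, 1), 0),
               -0.5 * log(2 * pi) - 0.5 * log(1^2 + 1.5))
  set.seed(12)
  for (r in 1:5) {
    X <- matrix(rnorm(20 * 4), 20)
    y <- rnorm(20)
    sf <- runif(1, 0.5, 2); sl <- runif(1, 0.5, 3); s2 <- runif(1, 0.01, 0.5)
    o <- denseGPOracle(X, y, X[1:2, , drop = FALSE], sf, sl, s2)
    expect_equal(logMarginalLikelihood(sf, sl, s2, X, y), o$logLik,
                 tolerance = 1e-8)
  }
})

test_that("likelihood in the noise parameter peaks near the true noise variance", {
  set.seed(9)
  n <- 50
  X <- matrix(rnorm(n * 2), n)
  y <- rnorm(n, 0, 0.5)  # pure noise, variance 0.25
  ll <- vapply(c(0.025, 0.25, 2.5), function(s2)
    logMarginalLikelihood(0.1, 1, s2, X, y), numeric(1))
  expect_gt(ll[2], ll[1])
  expect_gt(ll[2], ll[3])
})

test_that("posterior mean and covariance match the dense oracle", {
  set.seed(21)
  n <- 40
  X <- matrix(rnorm(n * 12), n)
  y <- sin(X[, 1]) + 0.05 * rnorm(n)
  Xs <- matrix(rnorm(6 * 12), 6)
  sf <- 1.1; sl <- 2.3; s2 <- 0.04
  fit <- fitGPRDirection(X, y, standardize = FALSE,
                         fixed = list(sigmaF = sf, sigmaL = sl, sigma2 = s2))
  p <- predictGPRDirection(fit, Xs, includeNoise = FALSE, fullCov = TRUE)
  o <- denseGPOracle(X, y, Xs, sf, sl, s2)
  expect_equal(p$mean, o$mean, tolerance = 1e-8)
  expect_equal(p$cov, o$cov, tolerance = 1e-8)
  expect_equal(fit@beta + fit@yCenter, o$beta, tolerance = 1e-8)
  # covariance symmetric PSD within tolerance
  expect_equal(p$cov, t(p$cov), tolerance = 1e-10)
  expect_gt(min(eigen(p$cov, symmetric = TRUE)$values), -1e-8)
  # posterior variance never exceeds prior variance
  expect_true(all(diag(p$cov) <= sf^2 + 1e-8))
  # predictive interval geometry
  p2 <- predictGPRDirection(fit, Xs)
  expect_equal(p2$ci95High - p2$mean, 1.96 * sqrt(p2$variance))
})

test_that("noise-free GP interpolates and reverts to the prior far away", {
  set.seed(33)
  n <- 15
  X <- matrix(runif(n * 12), n)
  y <- rnorm(n)
  fit <- fitGPRDirection(X, y, standardize = FALSE,
                         fixed = list(sigmaF = 1.5, sigmaL = 1.0,
                                      sigma2 = 0))
  p <- predictGPRDirection(fit, X, includeNoise = FALSE)
  expect_equal(p$mean, y, tolerance = 1e-6)
  far <- matrix(100, 2, 12)
  pf <- predictGPRDirection(fit, far, includeNoise = TRUE)
  expect_equal(pf$mean, rep(fit@beta + fit@yCenter, 2), tolerance = 1e-8)
  expect_equal(pf$variance,
               rep(1.5^2 + fit@hyp[["sigma2"]], 2), tolerance = 1e-6)
})

test_that("marginal-likelihood optimization ascends from its initialization", {
  set.seed(14)
  X <- matrix(rnorm(80 * 3), 80)
  y <- sin(2 * X[, 1]) + X[, 2]^2 * 0.3 + rnorm(80, 0, 0.1)
  fit <- fitGPRDirection(X, y, maxit = 60)
  expect_gte(fit@logLik, fit@logLik0)
  # Cholesky factor reproduces K + sigma2 I (+ jitter)
  h <- hyperparams(fit)
  Kn <- soleGRF:::seKernelMatrix(fit@X, fit@X, h["sigmaF"], h["sigmaL"]) +
    diag(h[["sigma2"]] + fit@jitter, nrow(fit@X))
  expect_lt(norm(crossprod(fit@cholK) - Kn, "F") / norm(Kn, "F"), 1e-8)
  # alpha solves the linear system
  resid <- Kn %*% fit@alpha - (fit@y - fit@beta)
  expect_lt(sqrt(sum(resid^2)) / sqrt(sum((fit@y - fit@beta)^2)), 1e-6)
})

test_that("zero response yields a null model", {
  set.seed(6)
  X <- matrix(rnorm(30 * 12), 30)
  fit <- fitGPRDirection(X, rep(0, 30), maxit = 30)
  expect_lt(abs(fit@beta), 1e-8)
  p <- predictGPRDirection(fit, X)
  expect_lt(max(abs(p$mean)), 1e-6)
})

test_that("duplicating every training point with doubled noise is near-invariant", {
  set.seed(19)
  n <- 40
  X <- matrix(rnorm(n * 4), n)
  y <- cos(X[, 1]) + 0.1 * rnorm(n)
  Xs <- matrix(rnorm(10 * 4), 10)
  f1 <- fitGPRDirection(X, y, standardize = FALSE,
                        fixed = list(sigmaF = 1, sigmaL = 1.5, sigma2 = 0.02))
  f2 <- fitGPRDirection(rbind(X, X), c(y, y), standardize = FALSE,
                        fixed = list(sigmaF = 1, sigmaL = 1.5, sigma2 = 0.04))
  p1 <- predictGPRDirection(f1, Xs)$mean
  p2 <- predictGPRDirection(f2, Xs)$mean
  expect_lt(sqrt(mean((p1 - p2)^2)) / sqrt(mean(p1^2)), 1e-3)
})

test_that("predictions agree with an independent reference GP implementation", {
  skip_if_not_installed("kernlab")
  set.seed(55)
  for (r in 1:10) {
    n <- 25; m <- 6; p <- 3
    X <- matrix(runif(n * p), n)
    Xs <- matrix(runif(m * p), m)
    y <- sin(3 * X[, 1]) + 0.1 * rnorm(n)
    sl <- runif(1, 0.4, 1.5); s2 <- runif(1, 0.01, 0.2)
    fit <- fitGPRDirection(X, y, standardize = FALSE, basis = "none",
                           fixed = list(sigmaF = 1, sigmaL = sl, sigma2 = s2))
    p1 <- predictGPRDirection(fit, Xs, includeNoise = FALSE)
    ref <- kernlab::gausspr(X, y, kernel = "rbfdot",
                            kpar = list(sigma = 1 / (2 * sl^2)), var = s2,
                            scaled = FALSE, variance.model = TRUE)
    expect_equal(p1$mean, drop(kernlab::predict(ref, Xs)), tolerance = 1e-6)
    expect_equal(sqrt(p1$variance),
                 drop(kernlab::predict(ref, Xs, type = "sdeviation")),
                 tolerance = 1e-6)
  }
})

test_that("GPR models survive a JSON round trip", {
  ds <- linearDataset(3, noiseSd = 0.3)
  model <- fitGPR(ds, directions = "z", trainRowCap = 150, maxit = 25)
  path <- tempfile(fileext = ".json")
  writeGPRModel(model, path)
  back <- readGPRModel(path)
  newX <- features(ds)[1:50, ]
  expect_equal(predict(back, newX)$mean, predict(model, newX)$mean,
               tolerance = 1e-8)
})
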