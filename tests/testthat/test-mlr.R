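test_that("OLS recovers exact linear data and matches normal equations", {
  set.seed(2)
  x1 <- rnorm(50)
  fit <- fitOLS(2 * x1 + 3, matrix(x1))
  expect_equal(fit$coef, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 3, tolerance = 1e-10)

  yc <- rep(4.2, 30)
  fitC <- fitOLS(yc, NULL)
  expect_equal(fitC$intercept, 4.2)
  expect_length(fitC$coef, 0)

  X <- matrix(rnorm(150), 50, 3)
  y <- rnorm(50)
  fit3 <- fitOLS(y, X)
  # brute-force normal-equations oracle
  Xm <- cbind(1, X)
  bHat <- solve(t(Xm) %*% Xm, t(Xm) %*% y)
  expect_equal(c(fit3$intercept, fit3$coef), drop(bHat), tolerance = 1e-8,
               ignore_attr = TRUE)

  Xdup <- cbind(a = X[, 1], b = X[, 1])
  expect_error(fitOLS(y, Xdup), "rank-deficient")
})

test_that("stepwise selection behaves under the null and under strong signal", {
  # agreement with the independent emptiness oracle, replicate by replicate
  set.seed(31)
  for (r in 1:25) {
    n <- 200
    X <- matrix(rnorm(n * 12), n)
    y <- rnorm(n)
    pv <- vapply(1:12, function(j) {
      f <- stats::lm.fit(cbind(1, X[, j]), y)
      rss1 <- sum(f$residuals^2)
      rss0 <- sum((y - mean(y))^2)
      stats::pf((rss0 - rss1) / (rss1 / (n - 2)), 1, n - 2,
                lower.tail = FALSE)
    }, numeric(1))
    sel <- stepwiseSelect(y, X)
    expect_identical(length(sel) == 0L, min(pv) >= 0.05)
  }
  # null empty-rate over 200 replicates: ~ (1 - 0.05)^12 ~ 0.54
  set.seed(42)
  emptyRate <- mean(replicate(200, {
    n <- 500
    length(stepwiseSelect(rnorm(n), matrix(rnorm(n * 12), n))) == 0L
  }))
  expect_gte(emptyRate, 0.40)
  expect_lte(emptyRate, 0.70)
})

test_that("stepwise finds a strong predictor and respects pEnter = 0", {
  set.seed(8)
  X <- matrix(rnorm(300 * 12), 300)
  y <- 5 * X[, 3] + rnorm(300, 0, 0.1)
  expect_true(3L %in% stepwiseSelect(y, X))
  expect_length(stepwiseSelect(y, X, pEnter = 0), 0L)
})

test_that("MLR reproduces exact linear target structure through the fit", {
  ds <- linearDataset(3)
  model <- fitMLR(ds)
  pred <- predict(model, features(ds))
  relRMS <- sqrt(colSums((pred - targets(ds))^2) / colSums(targets(ds)^2))
  expect_true(all(relRMS < 1e-6))
  # determinism: identical refit
  model2 <- fitMLR(ds)
  for (d in c("x", "y", "z")) {
    expect_identical(model@fits[[d]]$selected, model2@fits[[d]]$selected)
    expect_identical(model@fits[[d]]$coef, model2@fits[[d]]$coef)
  }
})

test_that("uniform replication of the data leaves the fit unchanged", {
  # exact linear targets: selection and coefficients are scale-free in n
  ds <- linearDataset(3)
  dsDup <- assembleDataset(c(splitToSteps(ds),
                             splitToSteps(ds, suffix = "b")))
  m1 <- fitMLR(ds)
  m2 <- fitMLR(dsDup)
  for (d in c("x", "y", "z")) {
    expect_identical(m1@fits[[d]]$selected, m2@fits[[d]]$selected)
    expect_equal(m1@fits[[d]]$coef, m2@fits[[d]]$coef, tolerance = 1e-8)
    expect_equal(m1@fits[[d]]$intercept, m2@fits[[d]]$intercept,
                 tolerance = 1e-8)
  }
})

test_that("MLR predictions reduce to intercepts for empty selections", {
  ds <- linearDataset(3, noiseSd = 0.5)
  model <- fitMLR(ds)
  zeroFeat <- matrix(0, 101, 12,
                     dimnames = list(NULL, soleGRF:::SENSOR_CHANNELS))
  predZero <- predict(model, zeroFeat)
  for (d in 1:3)
    expect_equal(unname(predZero[, d]),
                 rep(model@fits[[d]]$intercept, 101))
  # empty model: pure noise responses at pEnter = 0
  mEmpty <- fitMLR(ds, pEnter = 0)
  predE <- predict(mEmpty, features(ds)[1:101, ])
  expect_equal(apply(predE, 2, stats::sd), c(Fx = 0, Fy = 0, Fz = 0))
  badFeat <- zeroFeat
  colnames(badFeat) <- paste0("c", 1:12)
  expect_error(predict(model, badFeat), "lacks selected columns")
})

test_that("coefficients converge to the true support as noise shrinks", {
  set.seed(77)
  n <- 1500
  X <- matrix(rnorm(n * 12), n,
              dimnames = list(NULL, soleGRF:::SENSOR_CHANNELS))
  kTrue <- c(2, 0, 0, -1.5, rep(0, 8))
  signalSd <- stats::sd(drop(X %*% kTrue))
  for (eps in c(0, 0.01, 0.1)) {
    y <- drop(X %*% kTrue) + 0.7 + rnorm(n, 0, eps * signalSd)
    sel <- stepwiseSelect(y, X)
    expect_true(all(c(1L, 4L) %in% sel))
    ols <- fitOLS(y, X[, sel, drop = FALSE])
    est <- stats::setNames(rep(0, 12), colnames(X))
    est[sel] <- ols$coef
    expect_equal(unname(est[c(1, 4)]), c(2, -1.5),
                 tolerance = max(0.02, 3 * eps))
  }
})

test_that("MLR models survive a JSON round trip", {
  ds <- linearDataset(3, noiseSd = 0.2)
  model <- fitMLR(ds)
  path <- tempfile(fileext = ".json")
  writeMLRModel(model, path)
  back <- readMLRModel(path)
  expect_equal(predict(back, features(ds)[1:101, ]),
               predict(model, features(ds)[1:101, ]), tolerance = 1e-12)
})
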