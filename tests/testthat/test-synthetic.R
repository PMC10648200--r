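test_that("GRF template vanishes at heel contact and toe-off", {
  for (mv in gaitMovements()) {
    expect_equal(unname(grfTemplate(mv, 0, mass = 58)[1, ]), c(0, 0, 0))
    expect_equal(unname(grfTemplate(mv, 1, mass = 58)[1, ]), c(0, 0, 0))
  }
  expect_error(grfTemplate("straight", -0.1, mass = 58), "\\[0, 1\\]")
  expect_error(grfTemplate("straight", 1.1, mass = 58), "\\[0, 1\\]")
})

test_that("mid-stance vertical force matches direct evaluation of the waveform model", {
  # hand evaluation of the template expression at s = 0.5, straight walking:
  # two main bumps at distance 0.25 (width 0.16) minus the full valley bump
  fzHand <- 58 * 9.81 *
    max(0, 2 * 1.1 * exp(-0.25^2 / (2 * 0.16^2)) - 0.4 * 1)
  got <- grfTemplate("straight", 0.5, mass = 58)
  expect_equal(got[1, "Fz"], c(Fz = fzHand), tolerance = 1e-12)
  expect_gt(fzHand, 100)  # double-peaked curve keeps a positive valley
})

test_that("vertical sensor channels conserve the vertical GRF when noise is off", {
  s <- seq(0, 1, length.out = 201)
  grf <- grfTemplate("side_step", s, mass = 60)
  ch <- sensorProjection(grf, s, noiseSd = 0)
  expect_equal(rowSums(ch[, 9:12]), unname(grf[, "Fz"]), tolerance = 1e-12)
  # zero vertical force -> all four vertical channels zero
  expect_equal(ch[1, 9:12], c(fz1 = 0, fz2 = 0, fz3 = 0, fz4 = 0))
})

test_that("sensor noise matches its stated per-channel-range model", {
  s <- seq(0, 1, length.out = 101)
  grf <- grfTemplate("straight", s, mass = 58)
  clean <- sensorProjection(grf, s, noiseSd = 0)
  ranges <- apply(clean[, 9:12], 2, function(x) diff(range(x)))
  predictedSd <- sqrt(sum((0.02 * ranges)^2))
  allRanges <- apply(clean, 2, function(x) diff(range(x)))
  set.seed(11)
  j <- 51  # one fixed mid-stance sample
  draws <- replicate(1e4, {
    noisy <- sensorProjection(grf[j, , drop = FALSE], s[j], noiseSd = 0.02,
                              noiseRanges = allRanges)
    sum(noisy[, 9:12]) - grf[j, "Fz"]
  })
  expect_lt(abs(sd(draws) - predictedSd) / predictedSd, 0.20)
})

test_that("trial generation is deterministic and padded sub-threshold", {
  cfg <- generatorConfig(nParticipants = 1, stepsPerMovement = 1)
  prof <- soleGRF:::drawParticipant(cfg, 1L)
  t1 <- generateTrial(prof, "cross_step", cfg, seed = 123L)
  t2 <- generateTrial(prof, "cross_step", cfg, seed = 123L)
  expect_identical(t1@sensor, t2@sensor)
  expect_identical(t1@forceplate, t2@forceplate)
  expect_identical(t1@markers, t2@markers)

  expect_true(all(t1@forceplate[, 3] >= 0))
  # baseline before/after stance stays strictly below both thresholds
  tS <- (seq_len(nrow(t1@sensor)) - 1) / t1@sensorRate
  out <- tS < cfg$pad - 0.01 | tS > cfg$pad + cfg$stanceDuration * 1.1 + 0.01
  expect_true(all(abs(rowSums(t1@sensor[out, 9:12])) < 15))
  tP <- (seq_len(nrow(t1@forceplate)) - 1) / t1@plateRate
  outP <- tP < cfg$pad - 0.01 | tP > cfg$pad + cfg$stanceDuration * 1.1 + 0.01
  expect_true(all(t1@forceplate[outP, 3] < 50))
})

test_that("zero-heading trials store the shoe-frame template on the plate", {
  cfg <- noiseFreeConfig("straight")
  tr <- generateDataset(cfg)[[1]]
  expect_equal(tr@headingAngle, 0)
  tP <- (seq_len(nrow(tr@forceplate)) - 1) / tr@plateRate
  sP <- (tP - cfg$pad) / cfg$stanceDuration
  inP <- sP >= 0 & sP <= 1
  tmpl <- grfTemplate("straight", sP[inP], tr@bodyMass)
  expect_equal(unname(tr@forceplate[inP, ]), unname(tmpl), tolerance = 1e-10)
})

test_that("side-step and cross-step differ only in the sign of the turn offset", {
  mk <- function(mv) {
    cfg <- noiseFreeConfig(mv)
    generateDataset(cfg)[[1]]  # same master seed -> same participant draws
  }
  trS <- mk("side_step"); trC <- mk("cross_step")
  expect_equal(trS@bodyMass, trC@bodyMass)
  # rotate both back to the shoe frame and compare mediolateral components
  shoeS <- rotateToShoeFrame(trS@forceplate, trS@headingAngle)
  shoeC <- rotateToShoeFrame(trC@forceplate, trC@headingAngle)
  common <- (shoeS[, 1] + shoeC[, 1]) / 2
  expect_equal(shoeS[, 1] - common, -(shoeC[, 1] - common), tolerance = 1e-9)
  # and the common part is the unsigned mediolateral base template
  cfg <- noiseFreeConfig("straight")
  tP <- (seq_len(nrow(trS@forceplate)) - 1) / trS@plateRate
  sP <- (tP - cfg$pad) / cfg$stanceDuration
  inP <- sP >= 0 & sP <= 1
  tmpl <- grfTemplate("straight", sP[inP], trS@bodyMass)
  expect_equal(unname(common[inP]), unname(tmpl[, "Fx"]), tolerance = 1e-9)
})

test_that("dataset generation is a pure function of its configuration", {
  cfg <- generatorConfig(nParticipants = 2, stepsPerMovement = 3)
  d1 <- generateDataset(cfg)
  d2 <- generateDataset(cfg)
  expect_equal(length(d1), 2 * 3 * 3)
  expect_identical(lapply(d1, function(t) t@sensor),
                   lapply(d2, function(t) t@sensor))
  seeds1 <- vapply(d1, function(t) t@seed, integer(1))
  cfg2 <- generatorConfig(nParticipants = 2, stepsPerMovement = 3,
                          masterSeed = 2L)
  seeds2 <- vapply(generateDataset(cfg2), function(t) t@seed, integer(1))
  expect_length(intersect(seeds1, seeds2), 0)
})

test_that("the 12 channels determine the GRF on the stance interior", {
  s <- seq(0.05, 0.95, length.out = 91)
  grf <- grfTemplate("cross_step", s, mass = 62)
  ch <- sensorProjection(grf, s, noiseSd = 0)
  w <- soleGRF:::sensorWindows(s)
  rho <- soleGRF:::shearRatios(s)
  fzHat <- rowSums(ch[, 9:12])
  fxHat <- rowSums(ch[, 1:4] - rho$x * (w * fzHat)) / 0.5
  fyHat <- rowSums(ch[, 5:8] - rho$y * (w * fzHat)) / 0.5
  expect_equal(fzHat, unname(grf[, "Fz"]), tolerance = 1e-9)
  expect_equal(fxHat, unname(grf[, "Fx"]), tolerance = 1e-9)
  expect_equal(fyHat, unname(grf[, "Fy"]), tolerance = 1e-9)
})

test_that("mediolateral variability calibration reproduces the study's SD pattern", {
  # full study scale: 8 participants x 10 steps per movement
  cfg <- generatorConfig(nParticipants = 8, stepsPerMovement = 10,
                         masterSeed = 7L)
  steps <- preprocessTrials(generateDataset(cfg))
  v <- variabilitySummary(steps)
  vx <- v[v$direction == "x", ]
  rownames(vx) <- vx$movement
  # calibration targets (N/kg): between 0.221, within 0.183 for cross-step
  expect_lt(abs(vx["cross_step", "betweenSd"] - 0.221) / 0.221, 0.30)
  expect_lt(abs(vx["cross_step", "withinSd"] - 0.183) / 0.183, 0.30)
  # ordering: cross-step most variable, straight least (within), with
  # side-step and straight comparable between participants
  expect_gt(vx["cross_step", "betweenSd"], vx["side_step", "betweenSd"])
  expect_gt(vx["cross_step", "betweenSd"], vx["straight", "betweenSd"])
  expect_gt(vx["cross_step", "withinSd"], vx["side_step", "withinSd"])
  expect_gt(vx["side_step", "withinSd"], vx["straight", "withinSd"])
})
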