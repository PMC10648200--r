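# Shared fixtures: all synthetic, built in code at test time.

zeroShape <- c(straight = 0, side_step = 0, cross_step = 0)

# Generator config with every stochastic component switched off: the
# waveform templates are then recovered exactly up to filtering and
# resampling.
noiseFreeConfig <- function(movements = gaitMovements(), nParticipants = 1L,
                            stepsPerMovement = 1L, ...) {
  generatorConfig(
    nParticipants = nParticipants, stepsPerMovement = stepsPerMovement,
    movements = movements, sensorNoiseSd = 0, withinAmpSd = 0,
    betweenAmpSd = 0, betweenShapeSd = zeroShape, withinShapeSd = zeroShape,
    headingNoiseSd = 0, stanceJitter = 0, baselineSensorSd = 0,
    baselinePlateSd = 0, ...)
}

# Build a StepDataset whose targets are an exact linear function of the
# features (plus optional noise), for exact-fit regression checks.
linearDataset <- function(nStepsTotal = 3L, noiseSd = 0, seed = 1L) {
  set.seed(seed)
  K <- matrix(0, 12, 3)
  K[9:12, 3] <- 1                    # Fz = sum of vertical channels
  K[5:8, 2] <- c(2, -1, 0.5, 1.5)    # arbitrary exact relations
  K[1:4, 1] <- c(1, 0.3, -0.7, 0.2)
  steps <- lapply(seq_len(nStepsTotal), function(i) {
    f <- matrix(rnorm(101 * 12), 101, 12,
                dimnames = list(NULL, soleGRF:::SENSOR_CHANNELS))
    t <- f %*% K + matrix(c(1, 2, 3), 101, 3, byrow = TRUE)
    if (noiseSd > 0) t <- t + matrix(rnorm(101 * 3, 0, noiseSd), 101, 3)
    colnames(t) <- soleGRF:::GRF_CHANNELS
    new("AlignedStep", features = f, targets = t, bodyMass = 60,
        movement = "straight", participantId = sprintf("P%02d", (i + 1) %/% 2),
        stepId = sprintf("S%02d", i), headingAngleUsed = 0,
        sensorWindow = c(0, 1), plateWindow = c(0, 1))
  })
  assembleDataset(steps)
}

# Plain AlignedStep with given target curves (features ignored downstream).
fakeStep <- function(targets, participant = "P01", step = "S01",
                     movement = "straight", mass = 60) {
  new("AlignedStep",
      features = matrix(0, 101, 12,
                        dimnames = list(NULL, soleGRF:::SENSOR_CHANNELS)),
      targets = targets, bodyMass = mass, movement = movement,
      participantId = participant, stepId = step, headingAngleUsed = 0,
      sensorWindow = c(0, 1), plateWindow = c(0, 1))
}

# Split a StepDataset back into AlignedStep objects (optionally renaming
# the steps so two copies can be stacked together).
splitToSteps <- function(ds, suffix = "") {
  blocks <- soleGRF:::stepBlocks(ds)
  lapply(seq_along(blocks), function(i) {
    rows <- blocks[[i]]
    meta <- stepMeta(ds)[rows[1], ]
    fakeStepWith(features(ds)[rows, ], targets(ds)[rows, ],
                 participant = meta$participant,
                 step = paste0(meta$step, suffix),
                 movement = meta$movement, mass = meta$bodyMass)
  })
}

fakeStepWith <- function(features, targets, participant, step, movement,
                         mass) {
  new("AlignedStep", features = features, targets = targets,
      bodyMass = mass, movement = movement, participantId = participant,
      stepId = step, headingAngleUsed = 0,
      sensorWindow = c(0, 1), plateWindow = c(0, 1))
}

# Direct dense-inverse GP oracle: posterior mean/covariance and log
# marginal likelihood via solve() and determinant(), independent of the
# package's Cholesky path. Constant basis with GLS beta-hat.
denseGPOracle <- function(X, y, Xs, sigmaF, sigmaL, sigma2,
                          useBasis = TRUE) {
  k <- function(A, B) {
    D2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    sigmaF^2 * exp(-0.5 * pmax(D2, 0) / sigmaL^2)
  }
  n <- nrow(X)
  Kn <- k(X, X) + diag(sigma2, n)
  Kinv <- solve(Kn)
  h <- rep(1, n)
  beta <- if (useBasis)
    drop(solve(t(h) %*% Kinv %*% h, t(h) %*% Kinv %*% y)) else 0
  r <- y - beta * h
  Kstar <- k(X, Xs)
  mu <- drop(t(Kstar) %*% Kinv %*% r) + beta
  Sigma <- k(Xs, Xs) - t(Kstar) %*% Kinv %*% Kstar
  ll <- -0.5 * drop(t(r) %*% Kinv %*% r) - 0.5 * n * log(2 * pi) -
    0.5 * as.numeric(determinant(Kn, logarithm = TRUE)$modulus)
  list(mean = mu, cov = Sigma, logLik = ll, beta = beta)
}
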