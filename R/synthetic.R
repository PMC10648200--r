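#' @include AllClasses.R
NULL

## Unit-height Gaussian bump used throughout the waveform templates.
gaussBump <- function(s, center, width) exp(-(s - center)^2 / (2 * width^2))

## Cosine taper forcing waveforms to zero at heel contact (s=0) and toe-off
## (s=1) over a fraction `tw` of the stance at each end.
cosineTaper <- function(s, tw = 0.03) {
  out <- rep(1, length(s))
  lo <- s < tw
  hi <- s > 1 - tw
  out[lo] <- 0.5 * (1 - cos(pi * s[lo] / tw))
  out[hi] <- 0.5 * (1 - cos(pi * (1 - s[hi]) / tw))
  out
}

#' Default waveform template parameters
#'
#' Parameters of the deterministic shoe-frame GRF waveform model. The
#' vertical component is a double-peaked curve (two Gaussian bumps at 25% and
#' 75% of stance minus a mid-stance valley bump), the anteroposterior
#' component a braking/propulsion couple, and the mediolateral component a
#' small base bump plus a turn-direction-signed offset bump. All components
#' are multiplied by body weight and tapered to zero at heel contact and
#' toe-off.
#'
#' @return Named list of template parameters (amplitudes in body-weight
#'   units, centers/widths in stance fraction, `g` in m/s^2).
#' @export
grfTemplateParams <- function() {
  list(
    A1 = 1.1, A2 = 1.1, A3 = 0.4,          # vertical bump amplitudes (BW)
    c1 = 0.25, c2 = 0.75, c3 = 0.50,       # vertical bump centers
    w1 = 0.16, w2 = 0.16, w3 = 0.12,       # vertical bump widths
    taper = 0.03,                          # taper fraction at each end
    apAmp = 0.20, apC1 = 0.22, apC2 = 0.80, apW = 0.10,  # anteroposterior
    mlBase = 0.06, mlC1 = 0.35, mlW1 = 0.20,             # mediolateral base
    turnOffset = 0.08, mlC2 = 0.55, mlW2 = 0.25,         # turn-signed bump
    g = 9.81)
}

## Smooth unit bump for additive mediolateral shape perturbations,
## normalized so that mean(|shape|) over the 101-point stance grid is 1:
## a perturbation coefficient of c N/kg then contributes exactly c to the
## stance-averaged |Fx|/mass deviation.
mlShapeCurve <- function(s) {
  raw <- gaussBump(s, 0.5, 0.25)
  norm <- mean(gaussBump(seq(0, 1, length.out = 101L), 0.5, 0.25))
  raw / norm
}

#' Deterministic shoe-frame GRF waveform template
#'
#' Evaluates the three-directional GRF waveform model at stance fractions
#' `s` for a participant of mass `mass`, scaled per direction by `scale`.
#' An optional additive mediolateral shape term (`mlShapeCoef`, N/kg on a
#' unit-mean-|.| bump) models participant- and step-level mediolateral
#' variability beyond amplitude scaling.
#'
#' @param movement movement label, one of `gaitMovements()`.
#' @param s numeric vector of stance fractions in [0, 1].
#' @param mass body mass, kg.
#' @param scale length-3 per-direction amplitude factors (x, y, z).
#' @param params template parameters, see [grfTemplateParams()].
#' @param mlShapeCoef additive mediolateral shape coefficient, N/kg.
#' @return length(s) x 3 matrix with columns Fx, Fy, Fz (newtons).
#' @examples
#' grfTemplate("straight", c(0, 0.25, 0.5, 0.75, 1), mass = 58)
#' @export
grfTemplate <- function(movement, s, mass, scale = c(1, 1, 1),
                        params = grfTemplateParams(), mlShapeCoef = 0) {
  if (any(s < 0 | s > 1)) stop("stance fraction s must lie in [0, 1]")
  if (mass <= 0) stop("mass must be positive")
  mv <- movementInfo(movement)
  p <- params
  bw <- mass * p$g
  tp <- cosineTaper(s, p$taper)

  fz <- pmax(0, p$A1 * gaussBump(s, p$c1, p$w1) +
                p$A2 * gaussBump(s, p$c2, p$w2) -
                p$A3 * gaussBump(s, p$c3, p$w3))
  fz <- bw * scale[3] * fz * tp

  fy <- bw * scale[2] * p$apAmp *
    (-gaussBump(s, p$apC1, p$apW) + gaussBump(s, p$apC2, p$apW)) * tp

  off <- if (mv$mediolateralSign == 0) 0 else p$turnOffset
  fx <- bw * scale[1] *
    (p$mlBase * gaussBump(s, p$mlC1, p$mlW1) +
     mv$mediolateralSign * off * gaussBump(s, p$mlC2, p$mlW2)) * tp
  fx <- fx + mass * mlShapeCoef * mlShapeCurve(s) * tp

  out <- cbind(fx, fy, fz)
  colnames(out) <- GRF_CHANNELS
  out
}

## Raised-cosine sensor activation windows over the stance. Site order:
## heel, first metatarsal, fifth metatarsal, toe. Normalized so the four
## windows sum to 1 at every stance fraction.
sensorWindows <- function(s) {
  centers <- c(0.15, 0.55, 0.50, 0.85)
  halfWidth <- 0.45
  w <- sapply(centers, function(ci) {
    d <- abs(s - ci)
    ifelse(d < halfWidth, 0.5 * (1 + cos(pi * d / halfWidth)), 0)
  })
  w <- matrix(w, nrow = length(s))
  w / rowSums(w)
}

## Smooth site-specific shear-to-vertical ratio curves (piecewise linear in
## s, |rho| <= 0.3): rhoY turns from braking-negative to propulsion-positive
## across the stance; rhoX stays small with site-dependent sign.
shearRatios <- function(s) {
  ry0 <- c(-0.25, -0.20, -0.20, -0.15)
  ry1 <- c( 0.05,  0.20,  0.18,  0.28)
  rx0 <- c( 0.08, -0.05,  0.10,  0.02)
  rx1 <- c( 0.02,  0.05, -0.08,  0.06)
  list(
    x = sapply(1:4, function(i) rx0[i] + (rx1[i] - rx0[i]) * s),
    y = sapply(1:4, function(i) ry0[i] + (ry1[i] - ry0[i]) * s))
}

#' Project shoe-frame GRFs onto the 12 sensor channels
#'
#' Distributes the vertical GRF over the four sensor sites through
#' normalized raised-cosine activation windows (so the four vertical
#' channels always sum to the vertical GRF when noise is off) and derives
#' shear channels from site-specific shear-to-vertical ratio curves plus a
#' windowed share of the shear GRFs. Optional Gaussian measurement noise is
#' added per channel with SD = `noiseSd` times that channel's noise-free
#' range.
#'
#' @param grf n x 3 shoe-frame GRF matrix (Fx, Fy, Fz), newtons.
#' @param s stance fractions of the n rows.
#' @param noiseSd measurement noise SD as a fraction of per-channel range
#'   (0 disables noise).
#' @param noiseRanges optional length-12 vector of per-channel ranges used
#'   to scale the noise; by default computed from this call's noise-free
#'   channels (supply the full-step ranges when projecting a subset of the
#'   stance).
#' @return n x 12 matrix of sensor channels (fx1..fx4, fy1..fy4, fz1..fz4).
#' @export
sensorProjection <- function(grf, s, noiseSd = 0, noiseRanges = NULL) {
  stopifnot(ncol(grf) == 3L, nrow(grf) == length(s), all(is.finite(grf)))
  w <- sensorWindows(s)
  rho <- shearRatios(s)
  fz <- w * grf[, 3L]
  fx <- rho$x * fz + 0.5 * grf[, 1L] * w
  fy <- rho$y * fz + 0.5 * grf[, 2L] * w
  out <- cbind(fx, fy, fz)
  colnames(out) <- SENSOR_CHANNELS
  if (noiseSd > 0) {
    rng <- if (is.null(noiseRanges))
      apply(out, 2L, function(col) diff(range(col)))
    else noiseRanges
    noise <- matrix(stats::rnorm(length(out)), nrow(out), ncol(out))
    out <- out + noise * rep(noiseSd * rng, each = nrow(out))
  }
  out
}

#' Synthetic gait generator configuration
#'
#' Assembles (and validates) the configuration of the synthetic gait
#' generator: cohort size, movement protocol, waveform template parameters,
#' noise and variability levels, and the master seed. Identical
#' configurations produce bit-identical datasets.
#'
#' Defaults emulate the study conditions at desk scale: body mass drawn from
#' N(58.0, 5.4^2) kg truncated to [40, 90]; ~20 degree heading change for
#' turns; sensor measurement noise at 2% of per-channel range; stance
#' duration 0.65 s jittered +/-10% per step. Mediolateral variability is
#' calibrated through movement-specific additive shape SDs
#' (between-participant 0.148/0.151/0.221 and within-participant
#' 0.089/0.121/0.183 N/kg for straight/side-step/cross-step).
#'
#' @param nParticipants number of participants.
#' @param stepsPerMovement steps recorded per participant and movement.
#' @param movements movement labels to simulate.
#' @param stanceDuration nominal stance duration, seconds.
#' @param stanceJitter uniform per-step relative jitter on stance duration.
#' @param sensorNoiseSd measurement noise SD, fraction of per-channel range
#'   (applied to sensor channels and force-plate channels alike).
#' @param withinAmpSd within-participant SD of per-step multiplicative
#'   amplitude scale (per direction).
#' @param betweenAmpSd between-participant SD of amplitude scale.
#' @param betweenShapeSd named per-movement SD (N/kg) of the
#'   between-participant additive mediolateral shape coefficient.
#' @param withinShapeSd named per-movement SD (N/kg) of the per-step
#'   additive mediolateral shape coefficient.
#' @param headingNoiseSd per-trial SD of the realized heading angle, degrees.
#' @param turnHeading absolute heading change of turning movements, degrees.
#' @param massMean,massSd,massRange body-mass distribution, kg.
#' @param pad sub-threshold baseline padding before and after stance, s.
#' @param baselineSensorSd,baselinePlateSd baseline noise SDs, newtons
#'   (clipped to stay strictly below the stance-detection thresholds).
#' @param markerSpeed walking speed used for marker progression, m/s.
#' @param shoeLength heel-to-toe marker distance, metres.
#' @param sensorRate,plateRate,markerRate stream sampling rates, Hz.
#' @param templateParams waveform parameters, see [grfTemplateParams()].
#' @param masterSeed integer master seed.
#' @return A validated configuration list of class `GaitGenConfig`.
#' @export
generatorConfig <- function(nParticipants = 3L,
                            stepsPerMovement = 4L,
                            movements = gaitMovements(),
                            stanceDuration = 0.65,
                            stanceJitter = 0.10,
                            sensorNoiseSd = 0.02,
                            withinAmpSd = 0.04,
                            betweenAmpSd = 0.07,
                            betweenShapeSd = c(straight = 0.148,
                                               side_step = 0.151,
                                               cross_step = 0.221),
                            withinShapeSd = c(straight = 0.089,
                                              side_step = 0.121,
                                              cross_step = 0.183),
                            headingNoiseSd = 1.0,
                            turnHeading = 20,
                            massMean = 58.0, massSd = 5.4,
                            massRange = c(40, 90),
                            pad = 0.15,
                            baselineSensorSd = 0.3,
                            baselinePlateSd = 0.5,
                            markerSpeed = 1.2,
                            shoeLength = 0.25,
                            sensorRate = 870, plateRate = 1000,
                            markerRate = 200,
                            templateParams = grfTemplateParams(),
                            masterSeed = 1L) {
  stopifnot(nParticipants >= 1L, stepsPerMovement >= 1L,
            length(movements) >= 1L, all(movements %in% gaitMovements()),
            stanceDuration > 0, stanceJitter >= 0, sensorNoiseSd >= 0,
            withinAmpSd >= 0, betweenAmpSd >= 0, headingNoiseSd >= 0,
            pad >= 0.1, massSd >= 0,
            ## seed-derivation slots: <= 99 participants/steps, <= 9 movements
            nParticipants <= 99L, stepsPerMovement <= 99L,
            length(movements) <= 9L)
  cfg <- list(
    nParticipants = as.integer(nParticipants),
    stepsPerMovement = as.integer(stepsPerMovement),
    movements = movements, stanceDuration = stanceDuration,
    stanceJitter = stanceJitter, sensorNoiseSd = sensorNoiseSd,
    withinAmpSd = withinAmpSd, betweenAmpSd = betweenAmpSd,
    betweenShapeSd = betweenShapeSd, withinShapeSd = withinShapeSd,
    headingNoiseSd = headingNoiseSd, turnHeading = turnHeading,
    massMean = massMean, massSd = massSd, massRange = massRange,
    pad = pad, baselineSensorSd = baselineSensorSd,
    baselinePlateSd = baselinePlateSd, markerSpeed = markerSpeed,
    shoeLength = shoeLength, sensorRate = sensorRate,
    plateRate = plateRate, markerRate = markerRate,
    templateParams = templateParams, masterSeed = as.integer(masterSeed))
  class(cfg) <- "GaitGenConfig"
  cfg
}

## Deterministic seed derivation: participant seeds use step slot 0, trial
## seeds (participant, movement, step) slots. Stays far below 2^31.
deriveSeed <- function(masterSeed, pIdx, mIdx = 0L, stepIdx = 0L) {
  as.integer((abs(masterSeed) %% 10000L) * 100000L +
             pIdx * 1000L + mIdx * 100L + stepIdx)
}

## Participant-level random effects, drawn once per participant.
drawParticipant <- function(cfg, pIdx) {
  set.seed(deriveSeed(cfg$masterSeed, pIdx))
  mass <- Inf
  while (mass < cfg$massRange[1] || mass > cfg$massRange[2])
    mass <- stats::rnorm(1, cfg$massMean, cfg$massSd)
  ampScale <- pmax(0.2, stats::rnorm(3, 1, cfg$betweenAmpSd))
  shapeB <- stats::rnorm(length(gaitMovements()), 0,
                         cfg$betweenShapeSd[gaitMovements()])
  names(shapeB) <- gaitMovements()
  list(participantId = sprintf("P%02d", pIdx), bodyMass = mass,
       amplitudeScale = ampScale, mlShapeBetween = shapeB,
       headingNoiseSd = cfg$headingNoiseSd)
}

#' Generate one synthetic gait trial
#'
#' Samples the waveform templates on the three native time grids. The
#' force-plate stream is expressed in the laboratory frame by applying the
#' inverse shoe-frame rotation with the trial's realized heading angle, so
#' preprocessing must undo it; heel/toe markers advance along the heading
#' direction (holding still during stance) with the heel-to-toe axis
#' oriented at the same angle. Streams are padded with strictly
#' sub-threshold baseline noise before and after the stance.
#'
#' @param profile participant profile list (as drawn by the dataset
#'   generator): participantId, bodyMass, amplitudeScale (length 3),
#'   mlShapeBetween (per movement, N/kg), headingNoiseSd (degrees).
#' @param movement movement label.
#' @param config generator configuration, see [generatorConfig()].
#' @param seed integer seed for this trial's random draws.
#' @return A \linkS4class{TrialRecording}.
#' @export
generateTrial <- function(profile, movement, config, seed) {
  cfg <- config
  set.seed(seed)
  mv <- movementInfo(movement, cfg$turnHeading)

  dur <- cfg$stanceDuration *
    (1 + stats::runif(1, -cfg$stanceJitter, cfg$stanceJitter))
  phi <- mv$headingAngle + stats::rnorm(1, 0, profile$headingNoiseSd)
  scale <- profile$amplitudeScale *
    pmax(0.2, stats::rnorm(3, 1, cfg$withinAmpSd))
  shapeCoef <- profile$mlShapeBetween[[movement]] +
    stats::rnorm(1, 0, cfg$withinShapeSd[[movement]])

  total <- 2 * cfg$pad + dur
  stanceFrac <- function(t) (t - cfg$pad) / dur

  ## --- sensor stream (870 Hz) ---
  tS <- seq(0, total, by = 1 / cfg$sensorRate)
  sS <- stanceFrac(tS)
  inS <- sS >= 0 & sS <= 1
  sensor <- matrix(0, length(tS), 12L, dimnames = list(NULL, SENSOR_CHANNELS))
  grfS <- grfTemplate(movement, sS[inS], profile$bodyMass, scale,
                      cfg$templateParams, shapeCoef)
  sensor[inS, ] <- sensorProjection(grfS, sS[inS], cfg$sensorNoiseSd)
  nOut <- sum(!inS)
  if (nOut > 0 && cfg$baselineSensorSd > 0)
    sensor[!inS, ] <- pmin(3, pmax(-3, matrix(
      stats::rnorm(nOut * 12L, 0, cfg$baselineSensorSd), nOut, 12L)))

  ## --- force-plate stream (1000 Hz), lab frame ---
  tP <- seq(0, total, by = 1 / cfg$plateRate)
  sP <- stanceFrac(tP)
  inP <- sP >= 0 & sP <= 1
  plate <- matrix(0, length(tP), 3L, dimnames = list(NULL, c("FX", "FY", "FZ")))
  grfP <- grfTemplate(movement, sP[inP], profile$bodyMass, scale,
                      cfg$templateParams, shapeCoef)
  if (cfg$sensorNoiseSd > 0) {
    rng <- apply(grfP, 2L, function(col) diff(range(col)))
    grfP <- grfP + matrix(stats::rnorm(length(grfP)), nrow(grfP), 3L) *
      rep(cfg$sensorNoiseSd * rng, each = nrow(grfP))
  }
  ## lab frame = inverse of the shoe-frame rotation applied in preprocessing
  plate[inP, ] <- rotateToShoeFrame(grfP, -phi)
  nOutP <- sum(!inP)
  if (nOutP > 0 && cfg$baselinePlateSd > 0)
    plate[!inP, ] <- pmin(5, pmax(-5, matrix(
      stats::rnorm(nOutP * 3L, 0, cfg$baselinePlateSd), nOutP, 3L)))
  plate[, 3L] <- pmax(plate[, 3L], 0)

  ## --- markers (200 Hz): progress along heading, foot still during stance ---
  tM <- seq(0, total, by = 1 / cfg$markerRate)
  phiRad <- phi * pi / 180
  u <- c(sin(phiRad), cos(phiRad))
  prog <- cfg$markerSpeed *
    (pmin(tM, cfg$pad) + pmax(tM - cfg$pad - dur, 0))
  heel <- cbind(prog * u[1], prog * u[2])
  toe <- cbind(heel[, 1] + cfg$shoeLength * u[1],
               heel[, 2] + cfg$shoeLength * u[2])
  markers <- cbind(heel, toe)
  colnames(markers) <- c("heelX", "heelY", "toeX", "toeY")

  new("TrialRecording",
      sensor = sensor, sensorRate = cfg$sensorRate,
      forceplate = plate, plateRate = cfg$plateRate,
      markers = markers, markerRate = cfg$markerRate,
      bodyMass = profile$bodyMass, participantId = profile$participantId,
      movement = movement, headingAngle = phi, seed = as.integer(seed))
}

#' Generate a full synthetic gait dataset
#'
#' Draws participant profiles (body mass, per-direction amplitude scales,
#' per-movement mediolateral shape effects) once per participant, then
#' generates `stepsPerMovement` trials per participant and movement with
#' deterministically derived seeds. A pure function of the configuration.
#'
#' @param config generator configuration, see [generatorConfig()].
#' @return List of \linkS4class{TrialRecording} objects, one per trial,
#'   ordered by participant, movement, step.
#' @export
generateDataset <- function(config) {
  cfg <- config
  trials <- list()
  for (pIdx in seq_len(cfg$nParticipants)) {
    profile <- drawParticipant(cfg, pIdx)
    for (mIdx in seq_along(cfg$movements)) {
      for (stepIdx in seq_len(cfg$stepsPerMovement)) {
        seed <- deriveSeed(cfg$masterSeed, pIdx, mIdx, stepIdx)
        tr <- generateTrial(profile, cfg$movements[mIdx], cfg, seed)
        trials[[length(trials) + 1L]] <- tr
      }
    }
  }
  trials
}
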