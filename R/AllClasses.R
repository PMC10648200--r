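#' @import methods
NULL

## Canonical channel layout shared by the whole pipeline: four triaxial
## sensors (1 heel, 2 first metatarsal, 3 fifth metatarsal, 4 toe), grouped
## by axis, then the three force-plate GRF components in the shoe frame.
SENSOR_CHANNELS <- c(paste0("fx", 1:4), paste0("fy", 1:4), paste0("fz", 1:4))
GRF_CHANNELS <- c("Fx", "Fy", "Fz")
GRF_DIRECTIONS <- c("x", "y", "z")

#' Supported movement labels
#'
#' The three gait movements of the protocol: straight walking, side-step
#' turning and cross-step turning. Turns change heading by about 20 degrees
#' and produce mirrored mediolateral force signatures.
#'
#' @return Character vector of the three movement labels.
#' @export
gaitMovements <- function() c("straight", "side_step", "cross_step")

#' Movement descriptor
#'
#' Heading angle and mediolateral sign convention for a movement label.
#' Side-step and cross-step turns share the ~20 degree heading change but
#' load the mediolateral axis with opposite sign.
#'
#' @param label One of `gaitMovements()`.
#' @param turnHeading Absolute heading change for turning movements, degrees.
#' @return List with `label`, `headingAngle` (degrees) and
#'   `mediolateralSign` (+1, -1, or 0 for straight).
#' @export
movementInfo <- function(label, turnHeading = 20) {
  label <- match.arg(label, gaitMovements())
  switch(label,
    straight   = list(label = label, headingAngle = 0, mediolateralSign = 0),
    side_step  = list(label = label, headingAngle = turnHeading,
                      mediolateralSign = +1),
    cross_step = list(label = label, headingAngle = turnHeading,
                      mediolateralSign = -1))
}

#' One gait trial's raw multi-rate recordings
#'
#' Container for the three simultaneously recorded streams of a single
#' force-plate strike: 12 shoe-sole sensor channels (870 Hz), triaxial
#' force-plate GRFs in the laboratory frame (1000 Hz) and planar heel/toe
#' marker trajectories (200 Hz), plus participant and movement metadata.
#'
#' @slot sensor numeric matrix, samples x 12 (fx1..fx4, fy1..fy4, fz1..fz4), newtons.
#' @slot sensorRate sampling rate of `sensor`, Hz.
#' @slot forceplate numeric matrix, samples x 3 (FX, FY, FZ lab frame), newtons.
#' @slot plateRate sampling rate of `forceplate`, Hz.
#' @slot markers numeric matrix, samples x 4 (heelX, heelY, toeX, toeY), metres.
#' @slot markerRate sampling rate of `markers`, Hz.
#' @slot bodyMass participant body mass, kg.
#' @slot participantId participant identifier.
#' @slot movement movement label, one of `gaitMovements()`.
#' @slot headingAngle heading angle actually realized in this trial, degrees.
#' @slot seed integer seed the trial was generated from (NA for measured data).
#' @export
setClass("TrialRecording",
  representation(
    sensor = "matrix", sensorRate = "numeric",
    forceplate = "matrix", plateRate = "numeric",
    markers = "matrix", markerRate = "numeric",
    bodyMass = "numeric", participantId = "character",
    movement = "character", headingAngle = "numeric", seed = "integer"))

setValidity("TrialRecording", function(object) {
  msg <- character()
  if (ncol(object@sensor) != 12L)
    msg <- c(msg, "sensor must have 12 columns (fx1..fz4)")
  if (ncol(object@forceplate) != 3L)
    msg <- c(msg, "forceplate must have 3 columns (FX, FY, FZ)")
  if (ncol(object@markers) != 4L)
    msg <- c(msg, "markers must have 4 columns (heelX, heelY, toeX, toeY)")
  if (any(object@forceplate[, 3L] < 0))
    msg <- c(msg, "vertical force-plate component FZ must be non-negative")
  for (r in c(object@sensorRate, object@plateRate, object@markerRate))
    if (!is.finite(r) || r <= 0) msg <- c(msg, "sampling rates must be positive")
  if (!(object@movement %in% gaitMovements()))
    msg <- c(msg, "unknown movement label")
  if (object@bodyMass <= 0) msg <- c(msg, "bodyMass must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TrialRecording", function(object) {
  cat("TrialRecording:", object@participantId, "/", object@movement, "\n")
  cat(sprintf("  sensor    %d x 12 @ %g Hz\n", nrow(object@sensor), object@sensorRate))
  cat(sprintf("  plate     %d x 3  @ %g Hz\n", nrow(object@forceplate), object@plateRate))
  cat(sprintf("  markers   %d x 4  @ %g Hz\n", nrow(object@markers), object@markerRate))
  cat(sprintf("  mass %.1f kg, heading %.2f deg, seed %s\n",
              object@bodyMass, object@headingAngle, object@seed))
})

#' One detected stance phase
#'
#' 1-based start/end sample indices of the longest contiguous supra-threshold
#' run in a thresholded force signal, together with which stream it indexes.
#'
#' @slot start first supra-threshold sample (1-based).
#' @slot end last supra-threshold sample (1-based).
#' @slot streamId label of the stream the indices refer to.
#' @export
setClass("StancePhase",
  representation(start = "integer", end = "integer", streamId = "character"))

setValidity("StancePhase", function(object) {
  if (object@start > object@end) "start must be <= end" else TRUE
})

setMethod("show", "StancePhase", function(object) {
  cat(sprintf("StancePhase [%d, %d] on %s (%d samples)\n",
              object@start, object@end, object@streamId,
              object@end - object@start + 1L))
})

#' One stance phase normalized to 101 points
#'
#' Features and targets of a single step after preprocessing: every channel
#' resampled onto 0,1,...,100 percent of its stream's stance window, with the
#' force-plate GRFs rotated into the shoe frame.
#'
#' @slot features 101 x 12 matrix of sensor channels, newtons.
#' @slot targets 101 x 3 matrix of shoe-frame GRFs (Fx, Fy, Fz), newtons.
#' @slot bodyMass participant body mass, kg.
#' @slot movement movement label.
#' @slot participantId participant identifier.
#' @slot stepId step identifier within participant x movement.
#' @slot headingAngleUsed heading angle used for the rotation, degrees.
#' @slot sensorWindow c(start, end) stance times on the sensor clock, seconds.
#' @slot plateWindow c(start, end) stance times on the plate clock, seconds.
#' @export
setClass("AlignedStep",
  representation(
    features = "matrix", targets = "matrix",
    bodyMass = "numeric", movement = "character",
    participantId = "character", stepId = "character",
    headingAngleUsed = "numeric",
    sensorWindow = "numeric", plateWindow = "numeric"))

setValidity("AlignedStep", function(object) {
  msg <- character()
  if (!identical(dim(object@features), c(101L, 12L)))
    msg <- c(msg, "features must be 101 x 12")
  if (!identical(dim(object@targets), c(101L, 3L)))
    msg <- c(msg, "targets must be 101 x 3")
  if (object@bodyMass <= 0) msg <- c(msg, "bodyMass must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AlignedStep", function(object) {
  cat(sprintf("AlignedStep %s/%s/%s: 101 x 12 features, 101 x 3 targets, heading %.2f deg\n",
              object@participantId, object@movement, object@stepId,
              object@headingAngleUsed))
})

#' Stacked regression dataset of aligned steps
#'
#' Row-wise stack of one or more `AlignedStep`s: the feature matrix `f`
#' (n x 12) and target matrix `F` (n x 3) of the regression problem, with
#' per-row metadata. Rows of one step are contiguous and ordered by stance
#' percent; n is always a multiple of 101.
#'
#' @slot features n x 12 sensor feature matrix, newtons.
#' @slot targets n x 3 shoe-frame GRF target matrix, newtons.
#' @slot meta data.frame with columns participant, movement, step, pct,
#'   bodyMass (one row per matrix row).
#' @export
setClass("StepDataset",
  representation(features = "matrix", targets = "matrix", meta = "data.frame"))

setValidity("StepDataset", function(object) {
  msg <- character()
  n <- nrow(object@features)
  if (nrow(object@targets) != n || nrow(object@meta) != n)
    msg <- c(msg, "features, targets and meta must have equal row counts")
  if (ncol(object@features) != 12L) msg <- c(msg, "features must have 12 columns")
  if (ncol(object@targets) != 3L) msg <- c(msg, "targets must have 3 columns")
  if (n %% 101L != 0L) msg <- c(msg, "row count must be a multiple of 101")
  need <- c("participant", "movement", "step", "pct", "bodyMass")
  if (!all(need %in% names(object@meta)))
    msg <- c(msg, paste("meta must contain:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

setMethod("show", "StepDataset", function(object) {
  cat(sprintf("StepDataset: %d rows (%d steps), movements: %s\n",
              nrow(object@features), nSteps(object),
              paste(unique(object@meta$movement), collapse = ", ")))
})

#' Stepwise multiple linear regression model
#'
#' Per-direction predictor subsets, least-squares coefficients and intercepts
#' mapping the 12 instantaneous sensor channels to each GRF component.
#'
#' @slot fits named list (x, y, z), each with elements `selected` (character
#'   vector of feature columns), `coef` (numeric vector over selected
#'   columns) and `intercept`.
#' @slot trainingN number of training rows.
#' @slot pEnter entry p-value threshold used by stepwise selection.
#' @slot pRemove removal p-value threshold used by stepwise selection.
#' @export
setClass("MLRModel",
  representation(fits = "list", trainingN = "integer",
                 pEnter = "numeric", pRemove = "numeric"))

setValidity("MLRModel", function(object) {
  msg <- character()
  if (!all(GRF_DIRECTIONS %in% names(object@fits)))
    msg <- c(msg, "fits must contain x, y and z entries")
  for (d in intersect(GRF_DIRECTIONS, names(object@fits))) {
    f <- object@fits[[d]]
    if (length(f$coef) != length(f$selected))
      msg <- c(msg, sprintf("direction %s: coef length != selected length", d))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "MLRModel", function(object) {
  cat("MLRModel (stepwise OLS), n =", object@trainingN, "\n")
  for (d in GRF_DIRECTIONS) {
    f <- object@fits[[d]]
    cat(sprintf("  %s: %d predictors [%s], intercept %.4g\n", d,
                length(f$selected), paste(f$selected, collapse = ","),
                f$intercept))
  }
})

#' Single-output Gaussian process regression fit
#'
#' Exact GP with constant basis and isotropic squared-exponential kernel for
#' one GRF direction: fitted hyperparameters, feature standardization
#' constants, and the training-set Cholesky factorization reused at
#' prediction time.
#'
#' @slot direction which GRF direction the fit targets ("x", "y" or "z").
#' @slot hyp named numeric: sigmaF (signal SD), sigmaL (length scale),
#'   sigma2 (noise variance), all on the standardized-feature scale.
#' @slot beta constant-basis coefficient (on the centered-response scale).
#' @slot yCenter training response mean added back at prediction.
#' @slot featCenter,featScale per-column standardization constants.
#' @slot X standardized training feature matrix (possibly row-subsampled).
#' @slot y centered training response.
#' @slot cholK upper-triangular Cholesky factor of K + sigma2*I (+ jitter).
#' @slot alpha solved vector (K + sigma2*I)^-1 (y - H beta).
#' @slot jitter jitter actually added to the diagonal.
#' @slot logLik maximized log marginal likelihood.
#' @slot logLik0 log marginal likelihood at the initialization.
#' @export
setClass("GPRFit",
  representation(
    direction = "character", hyp = "numeric", beta = "numeric",
    yCenter = "numeric", featCenter = "numeric", featScale = "numeric",
    X = "matrix", y = "numeric", cholK = "matrix", alpha = "numeric",
    jitter = "numeric", logLik = "numeric", logLik0 = "numeric"))

setValidity("GPRFit", function(object) {
  msg <- character()
  if (!all(c("sigmaF", "sigmaL", "sigma2") %in% names(object@hyp)))
    msg <- c(msg, "hyp must contain sigmaF, sigmaL, sigma2")
  else if (any(object@hyp[c("sigmaF", "sigmaL")] <= 0))
    msg <- c(msg, "sigmaF and sigmaL must be positive")
  if (length(object@alpha) != nrow(object@X))
    msg <- c(msg, "alpha length must match training rows")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GPRFit", function(object) {
  cat(sprintf(
    "GPRFit [%s]: n = %d, sigmaF = %.4g, sigmaL = %.4g, sigma2 = %.4g, logLik = %.2f\n",
    object@direction, nrow(object@X), object@hyp["sigmaF"],
    object@hyp["sigmaL"], object@hyp["sigma2"], object@logLik))
})

#' Multi-direction Gaussian process regression model
#'
#' Independent single-output GP fits, one per requested GRF direction.
#'
#' @slot fits named list of \linkS4class{GPRFit} objects.
#' @slot trainingN rows available before any subsampling cap.
#' @export
setClass("GPRModel", representation(fits = "list", trainingN = "integer"))

setMethod("show", "GPRModel", function(object) {
  cat("GPRModel, training rows =", object@trainingN, "\n")
  for (f in object@fits) show(f)
})
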