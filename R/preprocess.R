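#' @include AllClasses.R
NULL

#' Zero-phase Butterworth low-pass filter
#'
#' Smooths a uniformly sampled force channel with a fourth-order Butterworth
#' low-pass filter (50 Hz cutoff by default), applied forward and backward
#' for zero phase lag. The series is extended at both ends by odd-symmetric
#' reflection before filtering (and trimmed afterwards) to suppress edge
#' transients, so output length equals input length.
#'
#' @param x numeric vector, one uniformly sampled channel.
#' @param fs sampling rate, Hz (must exceed twice the cutoff).
#' @param cutoff cutoff frequency, Hz.
#' @param order filter order.
#' @return Filtered vector of the same length as `x`.
#' @export
lowpass <- function(x, fs, cutoff = 50, order = 4L) {
  if (fs <= 2 * cutoff)
    stop("sampling rate must exceed twice the cutoff frequency")
  n <- length(x)
  minLen <- 3L * 3L * (order + 1L)
  if (n <= minLen)
    stop(sprintf("series too short for zero-phase filtering (need > %d samples)",
                 minLen))
  ## reflection long enough to absorb the filter's startup transient
  padlen <- min(10L * as.integer(ceiling(fs / cutoff)), n - 1L)
  pre <- 2 * x[1] - x[(padlen + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - padlen)]
  xx <- c(pre, x, post)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  yy <- signal::filtfilt(bf, xx)
  yy[(padlen + 1L):(padlen + n)]
}

#' Detect the stance phase by force threshold
#'
#' Returns the longest contiguous run of samples at or above `threshold`.
#' For the sole-sensor stream the thresholded signal is the sum of the four
#' vertical channels with a 15 N threshold; for the force plate it is the
#' vertical component with a 50 N threshold.
#'
#' @param x numeric vector, the thresholded signal (newtons).
#' @param threshold force threshold, newtons.
#' @param streamId label recorded in the result.
#' @return A \linkS4class{StancePhase} with 1-based start/end indices.
#' @export
detectStance <- function(x, threshold, streamId = "signal") {
  above <- x >= threshold
  if (!any(above)) stop("no stance detected: no sample reaches the threshold")
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  lens <- r$lengths[runs]
  best <- which(lens == max(lens))
  if (length(best) > 1L)
    stop("ambiguous stance: multiple equal-length supra-threshold runs")
  k <- runs[best]
  new("StancePhase", start = as.integer(starts[k]), end = as.integer(ends[k]),
      streamId = streamId)
}

#' Heading angle from heel/toe markers
#'
#' Signed planar angle, in degrees, between the mean toe-minus-heel vector
#' over the stance window and the laboratory +Y axis (positive towards +X,
#' returned in (-180, 180]).
#'
#' @param markers n x 4 matrix (heelX, heelY, toeX, toeY), metres.
#' @param frames indices of the marker frames inside the stance window
#'   (default: all frames).
#' @return Heading angle phi in degrees.
#' @export
headingAngle <- function(markers, frames = seq_len(nrow(markers))) {
  if (length(frames) < 3L)
    stop("need at least 3 marker frames within the stance window")
  v <- c(mean(markers[frames, 3L] - markers[frames, 1L]),
         mean(markers[frames, 4L] - markers[frames, 2L]))
  if (sqrt(sum(v^2)) < 1e-3)
    stop("heel and toe markers coincide: heading undefined")
  phi <- atan2(v[1], v[2]) * 180 / pi
  if (phi <= -180) phi <- phi + 360
  phi
}

#' Rotate laboratory-frame GRFs into the shoe frame
#'
#' Applies, row-wise, the planar rotation
#' \deqn{[F_x, F_y, F_z]^T = R(\phi) [F_X, F_Y, F_Z]^T}
#' with \eqn{R(\phi) = [[\cos\phi, \sin\phi, 0], [-\sin\phi, \cos\phi, 0],
#' [0, 0, 1]]}; the vertical component is unchanged.
#'
#' @param Flab n x 3 matrix of lab-frame GRFs.
#' @param phi heading angle, degrees.
#' @return n x 3 matrix in the shoe frame.
#' @export
rotateToShoeFrame <- function(Flab, phi) {
  stopifnot(is.finite(phi))
  a <- phi * pi / 180
  R <- matrix(c(cos(a), sin(a), 0,
                -sin(a), cos(a), 0,
                0, 0, 1), 3L, 3L, byrow = TRUE)
  out <- Flab %*% t(R)
  colnames(out) <- GRF_CHANNELS
  out
}

## Resample one channel onto `nOut` equally spaced points of [start, end]
## (sample indices). Linear by default; cubic spline optionally.
resampleChannel <- function(x, start, end, nOut = 101L,
                            method = c("linear", "spline")) {
  method <- match.arg(method)
  xout <- seq(start, end, length.out = nOut)
  idx <- start:end
  if (method == "linear")
    stats::approx(idx, x[idx], xout = xout)$y
  else
    stats::spline(idx, x[idx], xout = xout)$y
}

#' Normalize one trial to a 101-point aligned step
#'
#' Full preprocessing of a raw trial: (1) low-pass filter the sensor and
#' force-plate force channels; (2) detect the stance phase independently on
#' each stream (sum of vertical sensor channels at 15 N; plate vertical at
#' 50 N); (3) estimate the heading angle from the heel/toe markers over the
#' plate stance window and rotate the plate GRFs into the shoe frame;
#' (4) resample every channel onto 101 equally spaced points of its own
#' stream's stance window (heel contact = 0%, toe-off = 100%).
#'
#' @param trial a \linkS4class{TrialRecording}.
#' @param cutoff low-pass cutoff, Hz.
#' @param sensorThresh stance threshold on the summed vertical sensor
#'   channels, newtons.
#' @param plateThresh stance threshold on the plate vertical component,
#'   newtons.
#' @param method resampling interpolation, "linear" or "spline".
#' @param stepId identifier stored in the result (default derived from the
#'   trial seed).
#' @return An \linkS4class{AlignedStep}.
#' @export
normalizeStep <- function(trial, cutoff = 50, sensorThresh = 15,
                          plateThresh = 50,
                          method = c("linear", "spline"), stepId = NULL) {
  method <- match.arg(method)
  sens <- apply(trial@sensor, 2L, lowpass, fs = trial@sensorRate,
                cutoff = cutoff)
  plate <- apply(trial@forceplate, 2L, lowpass, fs = trial@plateRate,
                 cutoff = cutoff)

  stS <- detectStance(rowSums(sens[, paste0("fz", 1:4), drop = FALSE]),
                      sensorThresh, "sensor")
  stP <- detectStance(plate[, 3L], plateThresh, "forceplate")
  if (stS@end - stS@start + 1L < 5L || stP@end - stP@start + 1L < 5L)
    stop("stance shorter than 5 samples")

  ## marker frames inside the plate stance window (wall clock)
  tWin <- (c(stP@start, stP@end) - 1L) / trial@plateRate
  tM <- (seq_len(nrow(trial@markers)) - 1L) / trial@markerRate
  frames <- which(tM >= tWin[1] & tM <= tWin[2])
  phi <- headingAngle(trial@markers, frames)

  shoe <- rotateToShoeFrame(plate, phi)

  featMat <- sapply(SENSOR_CHANNELS, function(ch)
    resampleChannel(sens[, ch], stS@start, stS@end, method = method))
  targMat <- sapply(GRF_CHANNELS, function(ch)
    resampleChannel(shoe[, ch], stP@start, stP@end, method = method))

  if (is.null(stepId))
    stepId <- if (is.na(trial@seed)) "S01"
              else sprintf("S%02d", trial@seed %% 100L)

  new("AlignedStep",
      features = featMat, targets = targMat,
      bodyMass = trial@bodyMass, movement = trial@movement,
      participantId = trial@participantId, stepId = stepId,
      headingAngleUsed = phi,
      sensorWindow = (c(stS@start, stS@end) - 1L) / trial@sensorRate,
      plateWindow = tWin)
}

#' Stack aligned steps into a regression dataset
#'
#' Vertically stacks the 101-row feature/target blocks of the given steps,
#' preserving per-row metadata (participant, movement, step, stance percent,
#' body mass). Rows of one step stay contiguous and ordered by stance
#' percent.
#'
#' @param steps list of \linkS4class{AlignedStep} objects.
#' @return A \linkS4class{StepDataset} with 101 x length(steps) rows.
#' @export
assembleDataset <- function(steps) {
  if (length(steps) < 1L) stop("need at least one aligned step")
  feats <- do.call(rbind, lapply(steps, function(s) s@features))
  targs <- do.call(rbind, lapply(steps, function(s) s@targets))
  meta <- do.call(rbind, lapply(steps, function(s)
    data.frame(participant = s@participantId, movement = s@movement,
               step = s@stepId, pct = 0:100, bodyMass = s@bodyMass,
               stringsAsFactors = FALSE)))
  new("StepDataset", features = feats, targets = targs, meta = meta)
}

#' Preprocess a list of trials
#'
#' Applies [normalizeStep()] to every trial, assigning step identifiers by
#' order within each participant x movement group.
#'
#' @param trials list of \linkS4class{TrialRecording} objects.
#' @param ... passed to [normalizeStep()].
#' @return List of \linkS4class{AlignedStep} objects.
#' @export
preprocessTrials <- function(trials, ...) {
  counter <- new.env(parent = emptyenv())
  lapply(trials, function(tr) {
    key <- paste(tr@participantId, tr@movement, sep = "|")
    k <- (if (is.null(counter[[key]])) 0L else counter[[key]]) + 1L
    counter[[key]] <- k
    normalizeStep(tr, ..., stepId = sprintf("S%02d", k))
  })
}

## Split a StepDataset into per-step row-index blocks, keyed by
## participant|movement|step.
stepBlocks <- function(dataset) {
  key <- paste(dataset@meta$participant, dataset@meta$movement,
               dataset@meta$step, sep = "|")
  split(seq_len(nrow(dataset@features)), factor(key, unique(key)))
}

## Subset a StepDataset by row indices (keeping whole steps is the caller's
## responsibility for validity: row count must stay a multiple of 101).
subsetRows <- function(dataset, rows) {
  new("StepDataset",
      features = dataset@features[rows, , drop = FALSE],
      targets = dataset@targets[rows, , drop = FALSE],
      meta = dataset@meta[rows, , drop = FALSE])
}
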