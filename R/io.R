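#' @include AllClasses.R
NULL

fmt9 <- function(x) signif(x, 9)

#' Write a trial to a per-trial directory
#'
#' Writes three CSV files (`sensor.csv`, `forceplate.csv`, `markers.csv`,
#' each with a leading time column) plus `meta.json` holding participant
#' id, body mass, movement, heading angle, seed and sampling rates. Floats
#' carry 9 significant digits.
#'
#' @param trial a \linkS4class{TrialRecording}.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeTrial <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(mat, rate, file) {
    time <- (seq_len(nrow(mat)) - 1L) / rate
    df <- data.frame(time = fmt9(time), fmt9(mat), check.names = FALSE)
    utils::write.csv(df, file.path(dir, file), row.names = FALSE,
                     quote = FALSE)
  }
  wr(trial@sensor, trial@sensorRate, "sensor.csv")
  wr(trial@forceplate, trial@plateRate, "forceplate.csv")
  wr(trial@markers, trial@markerRate, "markers.csv")
  meta <- list(participant_id = trial@participantId,
               body_mass_kg = trial@bodyMass,
               movement = trial@movement,
               heading_angle_deg = trial@headingAngle,
               seed = trial@seed,
               sensor_rate_hz = trial@sensorRate,
               plate_rate_hz = trial@plateRate,
               marker_rate_hz = trial@markerRate)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a trial from a per-trial directory written by [writeTrial()]
#'
#' @param dir trial directory.
#' @return A \linkS4class{TrialRecording}.
#' @export
readTrial <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  rd <- function(file) {
    df <- utils::read.csv(file.path(dir, file), check.names = FALSE)
    as.matrix(df[, -1L, drop = FALSE])
  }
  new("TrialRecording",
      sensor = rd("sensor.csv"), sensorRate = meta$sensor_rate_hz,
      forceplate = rd("forceplate.csv"), plateRate = meta$plate_rate_hz,
      markers = rd("markers.csv"), markerRate = meta$marker_rate_hz,
      bodyMass = meta$body_mass_kg, participantId = meta$participant_id,
      movement = meta$movement, headingAngle = meta$heading_angle_deg,
      seed = as.integer(meta$seed))
}

#' Write aligned steps to the interchange CSV
#'
#' One row per stance percent and step, columns participant, movement,
#' step, bodyMass, pct, the 12 sensor channels and the 3 shoe-frame GRFs.
#'
#' @param steps list of \linkS4class{AlignedStep} objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeAlignedSteps <- function(steps, path) {
  ds <- assembleDataset(steps)
  df <- data.frame(ds@meta[c("participant", "movement", "step", "bodyMass",
                             "pct")],
                   fmt9(ds@features), fmt9(ds@targets), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read aligned steps written by [writeAlignedSteps()]
#'
#' @param path CSV path.
#' @return A \linkS4class{StepDataset}.
#' @export
readAlignedSteps <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  need <- c("participant", "movement", "step", "bodyMass", "pct",
            SENSOR_CHANNELS, GRF_CHANNELS)
  if (!all(need %in% names(df)))
    stop("aligned-steps file lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  new("StepDataset",
      features = as.matrix(df[SENSOR_CHANNELS]),
      targets = as.matrix(df[GRF_CHANNELS]),
      meta = df[c("participant", "movement", "step", "pct", "bodyMass")])
}
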