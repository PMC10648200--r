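#' @include AllClasses.R
NULL

## Tiny polynomial rolling hash of a config's deparsed form, for tagging
## outputs (stays within exact double-precision integer arithmetic).
configHash <- function(config) {
  txt <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  h <- 17
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Assemble an end-to-end run configuration
#'
#' Bundles the generator configuration with preprocessing, model and
#' evaluation parameters. Absent fields take the documented defaults.
#'
#' @param generator generator configuration, see [generatorConfig()].
#' @param cutoff low-pass cutoff, Hz.
#' @param sensorThresh,plateThresh stance thresholds, newtons.
#' @param interpolation "linear" or "spline" resampling.
#' @param pEnter,pRemove stepwise thresholds.
#' @param trainRowCap,maxit,nRestarts GP fitting controls.
#' @param kGPR predictor count attributed to GPR in adjusted R-squared.
#' @param models models to evaluate, subset of c("mlr", "gpr").
#' @param groupings dataset groupings, subset of c("movement", "all").
#' @return Configuration list of class `GRFRunConfig`.
#' @export
runConfig <- function(generator = generatorConfig(),
                      cutoff = 50, sensorThresh = 15, plateThresh = 50,
                      interpolation = "linear",
                      pEnter = 0.05, pRemove = 0.10,
                      trainRowCap = 600L, maxit = 60L, nRestarts = 0L,
                      kGPR = 12L,
                      models = c("mlr", "gpr"),
                      groupings = c("movement", "all")) {
  stopifnot(all(models %in% c("mlr", "gpr")),
            all(groupings %in% c("movement", "all")))
  cfg <- list(generator = generator, cutoff = cutoff,
              sensorThresh = sensorThresh, plateThresh = plateThresh,
              interpolation = interpolation, pEnter = pEnter,
              pRemove = pRemove, trainRowCap = as.integer(trainRowCap),
              maxit = as.integer(maxit), nRestarts = as.integer(nRestarts),
              kGPR = as.integer(kGPR), models = models,
              groupings = groupings)
  class(cfg) <- "GRFRunConfig"
  cfg
}

#' Run the full experiment
#'
#' Simulate, preprocess, and for every requested grouping (one dataset per
#' movement, plus the pooled all-movement dataset) and model, run
#' leave-one-step-out cross-validation and summarize the metrics. When
#' `outDir` is given, writes the aligned steps, per-fold metrics, summary
#' tables, the effective configuration, and a run log (all tagged with the
#' configuration hash); trials themselves are written only with
#' `writeTrials = TRUE`.
#'
#' @param config run configuration from [runConfig()].
#' @param outDir optional output directory.
#' @param writeTrials also write every raw trial directory.
#' @param verbose print stage progress and summary tables.
#' @return List with `steps`, `datasets`, `folds`, `metrics`, `summary`
#'   (the combined summary data.frame), `variability` and `configHash`,
#'   invisibly.
#' @export
runExperiment <- function(config = runConfig(), outDir = NULL,
                          writeTrials = FALSE, verbose = FALSE) {
  hash <- configHash(config)
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, paste0(format(Sys.time(), "%H:%M:%S "), msg))
    if (verbose) message(msg)
  }

  say("simulate: %d participants x %d steps x %d movements [config %s]",
      config$generator$nParticipants, config$generator$stepsPerMovement,
      length(config$generator$movements), hash)
  trials <- generateDataset(config$generator)

  say("preprocess: %d trials", length(trials))
  steps <- preprocessTrials(trials, cutoff = config$cutoff,
                            sensorThresh = config$sensorThresh,
                            plateThresh = config$plateThresh,
                            method = config$interpolation)

  movements <- config$generator$movements
  datasets <- list()
  if ("movement" %in% config$groupings)
    for (mv in movements)
      datasets[[mv]] <- assembleDataset(
        Filter(function(s) s@movement == mv, steps))
  if ("all" %in% config$groupings && length(movements) > 1L)
    datasets[["all"]] <- assembleDataset(steps)

  folds <- list()
  metrics <- list()
  summaries <- list()
  for (dsName in names(datasets)) {
    for (model in config$models) {
      say("loocv: dataset=%s model=%s (%d steps)", dsName, model,
          nSteps(datasets[[dsName]]))
      fr <- loocv(datasets[[dsName]], model = model,
                  kGPR = config$kGPR, pEnter = config$pEnter,
                  pRemove = config$pRemove,
                  trainRowCap = config$trainRowCap, maxit = config$maxit,
                  nRestarts = config$nRestarts,
                  seed = config$generator$masterSeed)
      key <- paste(dsName, model, sep = ".")
      folds[[key]] <- fr
      mt <- foldMetrics(fr)
      metrics[[key]] <- mt
      sm <- summarizeFolds(mt, grouping = if (dsName == "all") "all"
                                          else "movement")
      summaries[[key]] <- sm
      if (verbose) formatSummary(sm)
    }
  }
  summary <- do.call(rbind, c(summaries, list(make.row.names = FALSE)))

  vari <- tryCatch(variabilitySummary(steps), error = function(e) NULL)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (writeTrials)
      for (i in seq_along(trials))
        writeTrial(trials[[i]], file.path(outDir, "trials",
                                          sprintf("trial%03d", i)))
    writeAlignedSteps(steps, file.path(outDir, "aligned_steps.csv"))
    writeTagged <- function(df, file) {
      path <- file.path(outDir, file)
      writeLines(paste0("# config_hash: ", hash), path)
      suppressWarnings(utils::write.table(
        df, path, append = TRUE, sep = ",", row.names = FALSE,
        quote = FALSE))
    }
    writeTagged(summary, "summary.csv")
    writeTagged(do.call(rbind, c(metrics, list(make.row.names = FALSE))),
                "fold_metrics.csv")
    if (!is.null(vari)) writeTagged(vari, "variability.csv")
    cfgPlain <- unclass(config)
    cfgPlain$generator <- unclass(cfgPlain$generator)
    yaml::write_yaml(cfgPlain, file.path(outDir, "config.yaml"))
    writeLines(c(paste0("# config_hash: ", hash), log),
               file.path(outDir, "run_log.txt"))
  }

  invisible(list(steps = steps, datasets = datasets, folds = folds,
                 metrics = metrics, summary = summary, variability = vari,
                 configHash = hash))
}
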