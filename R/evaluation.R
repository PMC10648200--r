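#' @include AllClasses.R
NULL

#' Mass-normalized mean absolute error
#'
#' \deqn{MAE = \frac{1}{n} \sum_j |F_j/m - \hat F_j/m|} in N/kg, where m is
#' the participant's body mass.
#'
#' @param measured,predicted force vectors of equal length, newtons.
#' @param bodyMass participant body mass, kg (> 0).
#' @return MAE in N/kg.
#' @export
mae <- function(measured, predicted, bodyMass) {
  stopifnot(length(measured) == length(predicted))
  if (bodyMass <= 0) stop("bodyMass must be positive")
  mean(abs(measured - predicted)) / bodyMass
}

#' Percent root-mean-square error
#'
#' RMSE normalized by the max-minus-min range of the measured series of the
#' evaluated step, in percent:
#' \deqn{\%RMSE = 100 \sqrt{\tfrac1n \sum_j (F_j - \hat F_j)^2} /
#'   (F_{max} - F_{min})}
#'
#' @param measured,predicted force vectors of equal length, newtons.
#' @return %RMSE in percent.
#' @export
pctRMSE <- function(measured, predicted) {
  stopifnot(length(measured) == length(predicted))
  rng <- max(measured) - min(measured)
  if (rng <= 0) stop("measured series is constant: %RMSE undefined")
  100 * sqrt(mean((measured - predicted)^2)) / rng
}

#' Degree-of-freedom-adjusted coefficient of determination
#'
#' \deqn{R^2 = 1 - \frac{\sum_j (F_j - \hat F_j)^2}{\sum_j (F_j - \bar F)^2}
#'   \cdot \frac{n - 1}{n - k - 1}} with k the number of predictors. May be
#' negative for poor fits.
#'
#' @param measured,predicted force vectors of equal length.
#' @param k predictor count.
#' @return Adjusted R-squared (scalar, at most 1).
#' @export
adjR2 <- function(measured, predicted, k) {
  n <- length(measured)
  stopifnot(length(predicted) == n, n > k + 1)
  tss <- sum((measured - mean(measured))^2)
  if (tss <= 0) stop("measured series has zero total sum of squares")
  rss <- sum((measured - predicted)^2)
  1 - (rss / tss) * ((n - 1) / (n - k - 1))
}

#' Leave-one-step-out cross-validation
#'
#' One fold per step: each fold retrains the requested model from scratch
#' (including stepwise selection for MLR, hyperparameter optimization for
#' GPR) on all remaining steps and predicts the held-out step's 101 rows.
#' Folds are independent and order-insensitive.
#'
#' @param dataset a \linkS4class{StepDataset} with at least 3 steps.
#' @param model "mlr" or "gpr".
#' @param directions GRF directions to evaluate.
#' @param kGPR predictor count attributed to the GPR model in adjusted
#'   R-squared (all 12 channels enter the kernel).
#' @param pEnter,pRemove stepwise thresholds (MLR).
#' @param trainRowCap,maxit,nRestarts GP fitting controls (GPR), see
#'   [fitGPR()].
#' @param seed base seed for GP restart perturbations (fold-indexed).
#' @return List of fold results; each element has `participant`,
#'   `movement`, `step`, `bodyMass`, `measured` and `predicted` (101 x
#'   directions), per-direction predictor counts `k`, and for GPR `ci95Low`,
#'   `ci95High`.
#' @export
loocv <- function(dataset, model = c("mlr", "gpr"),
                  directions = GRF_DIRECTIONS, kGPR = 12L,
                  pEnter = 0.05, pRemove = 0.10,
                  trainRowCap = 600L, maxit = 60L, nRestarts = 0L,
                  seed = 1L) {
  model <- match.arg(model)
  blocks <- stepBlocks(dataset)
  if (length(blocks) < 3L) stop("need at least 3 steps for cross-validation")
  dcols <- match(directions, GRF_DIRECTIONS)

  lapply(seq_along(blocks), function(i) {
    testRows <- blocks[[i]]
    train <- subsetRows(dataset, -testRows)
    testFeat <- dataset@features[testRows, , drop = FALSE]
    measured <- dataset@targets[testRows, dcols, drop = FALSE]
    metaRow <- dataset@meta[testRows[1L], ]

    if (model == "mlr") {
      fit <- fitMLR(train, pEnter = pEnter, pRemove = pRemove)
      predAll <- predict(fit, testFeat)
      predicted <- predAll[, dcols, drop = FALSE]
      kPer <- vapply(directions, function(d)
        length(fit@fits[[d]]$selected), integer(1))
      ci95Low <- ci95High <- NULL
    } else {
      fit <- fitGPR(train, directions = directions,
                    trainRowCap = trainRowCap, maxit = maxit,
                    nRestarts = nRestarts, restartSeed = seed + i)
      pr <- predict(fit, testFeat)
      predicted <- pr$mean
      ci95Low <- pr$ci95Low
      ci95High <- pr$ci95High
      kPer <- stats::setNames(rep(as.integer(kGPR), length(directions)),
                              directions)
    }
    colnames(predicted) <- directions
    colnames(measured) <- directions
    list(participant = metaRow$participant, movement = metaRow$movement,
         step = metaRow$step, bodyMass = metaRow$bodyMass,
         model = model, measured = measured, predicted = predicted,
         k = kPer, ci95Low = ci95Low, ci95High = ci95High)
  })
}

#' Per-fold, per-direction evaluation metrics
#'
#' Computes MAE (N/kg), %RMSE and adjusted R-squared for every fold and
#' direction of a [loocv()] result.
#'
#' @param folds list of fold results from [loocv()].
#' @return data.frame with one row per fold x direction.
#' @export
foldMetrics <- function(folds) {
  rows <- lapply(folds, function(f) {
    dirs <- colnames(f$predicted)
    do.call(rbind, lapply(dirs, function(d) {
      m <- f$measured[, d]
      p <- f$predicted[, d]
      data.frame(participant = f$participant, movement = f$movement,
                 step = f$step, model = f$model, direction = d,
                 mae = mae(m, p, f$bodyMass), pctRMSE = pctRMSE(m, p),
                 adjR2 = adjR2(m, p, f$k[[d]]),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Summarize fold metrics into a results table
#'
#' Mean and sample standard deviation (n-1 denominator) of each metric
#' across folds, per group and direction, in the layout of the study's
#' results tables.
#'
#' @param metrics data.frame from [foldMetrics()].
#' @param grouping "movement" (per-movement rows) or "all" (one pooled
#'   group labelled "all").
#' @return data.frame keyed by (gait, model, direction) with mean/sd columns
#'   for MAE, %RMSE and adjusted R-squared, plus the fold count.
#' @export
summarizeFolds <- function(metrics, grouping = c("movement", "all")) {
  grouping <- match.arg(grouping)
  gait <- if (grouping == "movement") metrics$movement else "all"
  keys <- unique(data.frame(gait = gait, model = metrics$model,
                            direction = metrics$direction,
                            stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sel <- gait == keys$gait[i] & metrics$model == keys$model[i] &
      metrics$direction == keys$direction[i]
    sub <- metrics[sel, ]
    if (nrow(sub) < 2L) {
      warning("group with fewer than 2 folds omitted: ",
              paste(unlist(keys[i, ]), collapse = "/"))
      return(NULL)
    }
    data.frame(keys[i, ], nFolds = nrow(sub),
               maeMean = mean(sub$mae), maeSd = stats::sd(sub$mae),
               pctRMSEMean = mean(sub$pctRMSE),
               pctRMSESd = stats::sd(sub$pctRMSE),
               adjR2Mean = mean(sub$adjR2), adjR2Sd = stats::sd(sub$adjR2),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Render a summary table as aligned text
#'
#' @param summary data.frame from [summarizeFolds()].
#' @return Character vector of formatted lines, invisibly; also printed.
#' @export
formatSummary <- function(summary) {
  lines <- sprintf(
    "%-11s %-4s %-3s  MAE %6.3f +/- %5.3f  %%RMSE %5.1f +/- %4.1f  R2 %6.3f +/- %5.3f  (n=%d)",
    summary$gait, toupper(summary$model), summary$direction,
    summary$maeMean, summary$maeSd, summary$pctRMSEMean, summary$pctRMSESd,
    summary$adjR2Mean, summary$adjR2Sd, summary$nFolds)
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Between- and within-participant variability of mass-normalized GRFs
#'
#' For each movement and direction: the within-participant SD is the SD
#' across a participant's steps, averaged over participants and the 101
#' stance percents; the between-participant SD is the SD across
#' participant-mean curves, averaged over stance percents. Forces are
#' divided by body mass (N/kg) before computing SDs.
#'
#' @param steps list of \linkS4class{AlignedStep} objects (at least 2
#'   participants with at least 2 steps each per movement).
#' @return data.frame with columns movement, direction, betweenSd, withinSd.
#' @export
variabilitySummary <- function(steps) {
  movs <- unique(vapply(steps, function(s) s@movement, character(1)))
  out <- list()
  for (mv in movs) {
    sub <- Filter(function(s) s@movement == mv, steps)
    parts <- vapply(sub, function(s) s@participantId, character(1))
    if (length(unique(parts)) < 2L)
      stop("need at least 2 participants per movement")
    for (d in seq_along(GRF_DIRECTIONS)) {
      ## participant -> steps x 101 matrix of mass-normalized force
      curves <- lapply(split(sub, parts), function(ss) {
        if (length(ss) < 2L)
          stop("need at least 2 steps per participant and movement")
        t(vapply(ss, function(s) s@targets[, d] / s@bodyMass,
                 numeric(101L)))
      })
      withinPer <- vapply(curves, function(M)
        mean(apply(M, 2L, stats::sd)), numeric(1))
      withinSd <- mean(withinPer)
      meanCurves <- t(vapply(curves, colMeans, numeric(101L)))
      betweenSd <- mean(apply(meanCurves, 2L, stats::sd))
      out[[length(out) + 1L]] <- data.frame(
        movement = mv, direction = GRF_DIRECTIONS[d],
        betweenSd = betweenSd, withinSd = withinSd,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Empirical coverage of GPR 95% prediction intervals
#'
#' Fraction of measured samples falling inside the per-fold 95% prediction
#' bands, pooled over folds and directions.
#'
#' @param folds list of GPR fold results from [loocv()].
#' @return Coverage fraction in [0, 1].
#' @export
ciCoverage <- function(folds) {
  hits <- 0L; total <- 0L
  for (f in folds) {
    if (is.null(f$ci95Low)) stop("folds carry no confidence intervals")
    hits <- hits + sum(f$measured >= f$ci95Low & f$measured <= f$ci95High)
    total <- total + length(f$measured)
  }
  hits / total
}
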