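#' @include AllClasses.R
NULL

#' Ordinary least squares with intercept
#'
#' Minimizes the residual sum of squares of `y ~ X` (intercept always
#' included) through the QR decomposition.
#'
#' @param y response vector.
#' @param X n x p predictor matrix (p may be 0 for an intercept-only fit).
#' @return List with `coef` (length p), `intercept`, and `rss`.
#' @export
fitOLS <- function(y, X) {
  n <- length(y)
  p <- if (is.null(X)) 0L else ncol(X)
  if (n <= p + 1L) stop("need more observations than parameters")
  if (p == 0L) {
    b <- mean(y)
    return(list(coef = numeric(0), intercept = b, rss = sum((y - b)^2)))
  }
  Xm <- cbind(`(Intercept)` = 1, X)
  fit <- stats::lm.fit(Xm, y)
  if (fit$rank < ncol(Xm)) {
    bad <- colnames(Xm)[is.na(fit$coefficients)]
    stop("rank-deficient predictor matrix; offending columns: ",
         paste(bad, collapse = ", "))
  }
  co <- fit$coefficients
  list(coef = unname(co[-1L]), intercept = unname(co[1L]),
       rss = sum(fit$residuals^2))
}

## RSS of the OLS fit on columns `cols` of X (intercept-only when empty).
rssOf <- function(y, X, cols) {
  if (length(cols) == 0L) return(sum((y - mean(y))^2))
  Xm <- cbind(1, X[, cols, drop = FALSE])
  f <- stats::lm.fit(Xm, y)
  sum(f$residuals^2)
}

#' Forward-backward stepwise predictor selection by partial F-tests
#'
#' Classical stepwise selection: starting from the intercept-only model,
#' repeatedly (a) add the candidate predictor with the smallest partial-F
#' p-value if it is below `pEnter`, then (b) remove the included predictor
#' with the largest partial-F p-value if it exceeds `pRemove`. Ties are
#' broken by the lower column index. Terminates when no addition or removal
#' is possible, or when a previously visited subset would recur.
#'
#' @param y response vector.
#' @param X n x p candidate predictor matrix.
#' @param pEnter entry threshold on the partial-F p-value.
#' @param pRemove removal threshold on the partial-F p-value.
#' @return Integer vector of selected column indices (possibly empty),
#'   in increasing order.
#' @export
stepwiseSelect <- function(y, X, pEnter = 0.05, pRemove = 0.10) {
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 2L) stop("need n > p + 2 observations for stepwise selection")
  sel <- integer(0)
  keyOf <- function(s) paste(sort(s), collapse = ",")
  visited <- keyOf(sel)
  tss <- sum((y - mean(y))^2)
  exactTol <- 1e-12 * max(tss, 1)
  repeat {
    changed <- FALSE
    rssCur <- rssOf(y, X, sel)

    ## forward: smallest partial-F p-value among candidates
    cand <- setdiff(seq_len(p), sel)
    if (length(cand) > 0L) {
      df2 <- n - length(sel) - 2L   # params of the larger model: |sel|+1 slopes + intercept
      pv <- vapply(cand, function(j) {
        if (rssCur <= exactTol) return(1)  # already an exact fit
        rssNew <- rssOf(y, X, c(sel, j))
        if (rssNew <= exactTol) return(0)  # candidate completes an exact fit
        Fj <- (rssCur - rssNew) / (rssNew / df2)
        stats::pf(Fj, 1, df2, lower.tail = FALSE)
      }, numeric(1))
      jBest <- cand[which.min(pv)]   # which.min takes the lowest index on ties
      if (min(pv) < pEnter) {
        newSel <- sort(c(sel, jBest))
        if (!(keyOf(newSel) %in% visited)) {
          sel <- newSel
          visited <- c(visited, keyOf(sel))
          rssCur <- rssOf(y, X, sel)
          changed <- TRUE
        }
      }
    }

    ## backward: largest partial-F p-value among included predictors
    if (length(sel) > 0L) {
      df2 <- n - length(sel) - 1L   # params of the current (larger) model
      pv <- vapply(sel, function(j) {
        rssDrop <- rssOf(y, X, setdiff(sel, j))
        if (rssCur <= exactTol)
          return(if (rssDrop <= exactTol) 1 else 0)
        Fj <- (rssDrop - rssCur) / (rssCur / df2)
        stats::pf(Fj, 1, df2, lower.tail = FALSE)
      }, numeric(1))
      worst <- max(pv)
      if (worst > pRemove) {
        jDrop <- sel[which.max(pv)]  # lowest index among tied maxima
        newSel <- setdiff(sel, jDrop)
        if (!(keyOf(newSel) %in% visited)) {
          sel <- newSel
          visited <- c(visited, keyOf(sel))
          changed <- TRUE
        }
      }
    }

    if (!changed) break
  }
  sort(sel)
}

#' Fit the stepwise multiple linear regression model
#'
#' For each GRF direction independently: select predictors among the 12
#' sensor channels by [stepwiseSelect()], then fit ordinary least squares on
#' the selected columns. Refitting on identical data yields identical
#' selections and coefficients.
#'
#' @param dataset a \linkS4class{StepDataset}.
#' @param pEnter,pRemove stepwise thresholds, see [stepwiseSelect()].
#' @return An \linkS4class{MLRModel}.
#' @export
fitMLR <- function(dataset, pEnter = 0.05, pRemove = 0.10) {
  X <- features(dataset)
  Y <- targets(dataset)
  fits <- lapply(seq_along(GRF_DIRECTIONS), function(d) {
    y <- Y[, d]
    sel <- stepwiseSelect(y, X, pEnter, pRemove)
    ols <- fitOLS(y, if (length(sel)) X[, sel, drop = FALSE] else NULL)
    list(selected = colnames(X)[sel], coef = ols$coef,
         intercept = ols$intercept)
  })
  names(fits) <- GRF_DIRECTIONS
  new("MLRModel", fits = fits, trainingN = nrow(X),
      pEnter = pEnter, pRemove = pRemove)
}

#' Predict GRFs with a fitted MLR model
#'
#' Row-wise affine map of the sensor features through each direction's
#' selected coefficients and intercept.
#'
#' @param object an \linkS4class{MLRModel}.
#' @param newdata m x 12 sensor feature matrix with the training column
#'   names.
#' @return m x 3 matrix of predicted GRFs (Fx, Fy, Fz).
#' @export
setMethod("predict", "MLRModel", function(object, newdata) {
  stopifnot(is.matrix(newdata), ncol(newdata) == 12L)
  out <- sapply(GRF_DIRECTIONS, function(d) {
    f <- object@fits[[d]]
    if (length(f$selected) == 0L)
      return(rep(f$intercept, nrow(newdata)))
    if (!all(f$selected %in% colnames(newdata)))
      stop("newdata lacks selected columns: ",
           paste(setdiff(f$selected, colnames(newdata)), collapse = ", "))
    drop(newdata[, f$selected, drop = FALSE] %*% f$coef) + f$intercept
  })
  out <- matrix(out, nrow = nrow(newdata), ncol = 3L,
                dimnames = list(NULL, GRF_CHANNELS))
  out
})

#' Serialize an MLR model to JSON
#'
#' @param model an \linkS4class{MLRModel}.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMLRModel <- function(model, path) {
  obj <- list(type = "MLRModel", trainingN = model@trainingN,
              pEnter = model@pEnter, pRemove = model@pRemove,
              fits = model@fits)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an MLR model serialized by [writeMLRModel()]
#'
#' @param path JSON file path.
#' @return An \linkS4class{MLRModel}.
#' @export
readMLRModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fits <- lapply(obj$fits, function(f)
    list(selected = as.character(f$selected), coef = as.numeric(f$coef),
         intercept = as.numeric(f$intercept)))
  new("MLRModel", fits = fits, trainingN = as.integer(obj$trainingN),
      pEnter = obj$pEnter, pRemove = obj$pRemove)
}
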