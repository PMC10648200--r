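#' @include AllClasses.R
NULL

#' Isotropic squared-exponential kernel
#'
#' \deqn{k(f_i, f_j) = \sigma_f^2 \exp(-\tfrac{1}{2} \|f_i - f_j\|^2 / \sigma_l^2)}
#'
#' @param fi,fj numeric vectors of equal length.
#' @param sigmaF signal standard deviation (> 0).
#' @param sigmaL characteristic length scale (> 0).
#' @return Kernel value (scalar).
#' @export
seKernel <- function(fi, fj, sigmaF, sigmaL) {
  stopifnot(sigmaF > 0, sigmaL > 0)
  sigmaF^2 * exp(-0.5 * sum((fi - fj)^2) / sigmaL^2)
}

## Squared Euclidean distance matrices, computed via cross products.
sqDistMatrix <- function(X, Y = X) {
  nx <- rowSums(X^2)
  ny <- rowSums(Y^2)
  d2 <- outer(nx, ny, "+") - 2 * tcrossprod(X, Y)
  pmax(d2, 0)
}

seKernelMatrix <- function(X, Y = X, sigmaF, sigmaL) {
  sigmaF^2 * exp(-0.5 * sqDistMatrix(X, Y) / sigmaL^2)
}

## Cholesky of K + sigma2*I with adaptive jitter: start at
## 1e-10 * mean(diag), escalate x10 up to 1e-4 * mean(diag).
cholWithJitter <- function(Kn) {
  base <- mean(diag(Kn))
  jit <- 0
  U <- tryCatch(chol(Kn), error = function(e) NULL)
  while (is.null(U)) {
    jit <- if (jit == 0) 1e-10 * base else jit * 10
    if (jit > 1e-4 * base)
      stop("Cholesky factorization failed even at maximum jitter")
    U <- tryCatch(chol(Kn + diag(jit, nrow(Kn))), error = function(e) NULL)
  }
  list(U = U, jitter = jit)
}

## Solve (K + sigma2 I) x = b given the upper Cholesky factor U.
cholSolve <- function(U, b) backsolve(U, backsolve(U, b, transpose = TRUE))

#' Generalized least-squares basis coefficient
#'
#' \deqn{\hat\beta = (H^T (K+\sigma^2 I)^{-1} H)^{-1} H^T (K+\sigma^2 I)^{-1} F}
#' computed through the Cholesky factor of \eqn{K+\sigma^2 I} (no explicit
#' inverse). `H` is the constant basis (a column of ones) unless supplied.
#'
#' @param Ksigma n x n positive-definite matrix \eqn{K+\sigma^2 I}.
#' @param F response vector of length n.
#' @param H n x q basis matrix (default: column of ones).
#' @return Basis coefficient(s), length q.
#' @export
betaHat <- function(Ksigma, F, H = matrix(1, nrow(Ksigma), 1L)) {
  U <- cholWithJitter(Ksigma)$U
  KiH <- cholSolve(U, H)
  KiF <- cholSolve(U, F)
  drop(solve(crossprod(H, KiH), crossprod(H, KiF)))
}

## Core likelihood/gradient evaluation on standardized data.
## par = (log sigmaF, log sigmaL, log sigmaN); returns negative log marginal
## likelihood (beta profiled out) and its gradient.
gprObjective <- function(par, y, D2, grad = FALSE) {
  n <- length(y)
  sf2 <- exp(2 * par[1])
  sl2 <- exp(2 * par[2])
  s2 <- exp(2 * par[3])
  K <- sf2 * exp(-0.5 * D2 / sl2)
  Kn <- K + diag(s2, n)
  cj <- cholWithJitter(Kn)
  U <- cj$U
  h <- rep(1, n)
  Kih <- cholSolve(U, h)
  Kiy <- cholSolve(U, y)
  beta <- sum(h * Kiy) / sum(h * Kih)
  r <- y - beta * h
  alpha <- Kiy - beta * Kih              # (K+s2 I)^-1 (y - H beta)
  ll <- -0.5 * sum(r * alpha) - 0.5 * n * log(2 * pi) - sum(log(diag(U)))
  if (!grad)
    return(list(nll = -ll, ll = ll, U = U, alpha = alpha, beta = beta,
                jitter = cj$jitter))
  Kinv <- chol2inv(U)
  A <- tcrossprod(alpha) - Kinv          # d ll / dK = A / 2 (envelope: beta profiled)
  gSf <- sum(A * K)                      # dK/dlog sigmaF = 2K
  gSl <- 0.5 * sum(A * (K * (D2 / sl2)))
  gSn <- s2 * sum(diag(A))
  list(nll = -ll, gradient = -c(gSf, gSl, gSn), ll = ll)
}

#' Log marginal likelihood of the GP model
#'
#' Evaluates, with the constant-basis coefficient profiled out by
#' generalized least squares,
#' \deqn{\log p(F) = -\tfrac12 (F-H\hat\beta)^T (K+\sigma^2 I)^{-1}
#'   (F-H\hat\beta) - \tfrac{n}{2}\log 2\pi - \tfrac12 \log|K+\sigma^2 I|}
#' with the log-determinant taken from the Cholesky diagonal.
#'
#' @param sigmaF,sigmaL kernel hyperparameters (> 0).
#' @param sigma2 noise variance (>= 0).
#' @param X n x p feature matrix (used as-is; no standardization here).
#' @param y response vector.
#' @return Log marginal likelihood (scalar).
#' @export
logMarginalLikelihood <- function(sigmaF, sigmaL, sigma2, X, y) {
  stopifnot(sigmaF > 0, sigmaL > 0, sigma2 >= 0)
  D2 <- sqDistMatrix(X)
  out <- gprObjective(log(c(sigmaF, sigmaL, sqrt(max(sigma2, 1e-300)))),
                      y, D2)
  if (!is.finite(out$ll))
    stop(sprintf("non-finite log-likelihood at sigmaF=%g sigmaL=%g sigma2=%g",
                 sigmaF, sigmaL, sigma2))
  out$ll
}

## Deterministic stratified row subsample: rows of a stacked step dataset
## are contiguous per step and ordered by stance percent, so evenly spaced
## indices cover all steps and stance percents.
capRows <- function(n, cap) {
  if (n <= cap) seq_len(n) else unique(round(seq(1, n, length.out = cap)))
}

#' Fit a Gaussian process regression model
#'
#' Fits one independent GP per requested GRF direction: features are
#' standardized per column and the response centered; the hyperparameters
#' (log signal SD, log length scale, log noise SD) maximize the log marginal
#' likelihood (constant-basis coefficient profiled out) by L-BFGS-B with
#' analytic gradients, starting from a data-driven initialization
#' (length scale = mean pairwise distance of a feature subsample; signal SD
#' = response SD; noise variance = 10% of response variance), with optional
#' random restarts. Training rows beyond `trainRowCap` are subsampled
#' deterministically, stratified by stance percent.
#'
#' @param dataset a \linkS4class{StepDataset}.
#' @param directions GRF directions to fit (subset of c("x", "y", "z")).
#' @param trainRowCap maximum training rows per fit.
#' @param maxit L-BFGS-B iteration cap.
#' @param nRestarts additional random restarts of the optimizer.
#' @param restartSeed seed for restart perturbations.
#' @param basis "constant" (default) or "none" (zero basis; mainly for
#'   cross-checks against reference implementations).
#' @return A \linkS4class{GPRModel}.
#' @export
fitGPR <- function(dataset, directions = GRF_DIRECTIONS, trainRowCap = 600L,
                   maxit = 60L, nRestarts = 0L, restartSeed = 1L,
                   basis = c("constant", "none")) {
  basis <- match.arg(basis)
  X <- features(dataset)
  Y <- targets(dataset)
  if (nrow(X) < 10L) stop("need at least 10 training rows")
  rows <- capRows(nrow(X), trainRowCap)
  fits <- lapply(directions, function(d)
    fitGPRDirection(X[rows, , drop = FALSE],
                    Y[rows, match(d, GRF_DIRECTIONS)], d,
                    maxit = maxit, nRestarts = nRestarts,
                    restartSeed = restartSeed, basis = basis))
  names(fits) <- directions
  new("GPRModel", fits = fits, trainingN = nrow(X))
}

#' Fit a single-direction GP on a raw feature matrix
#'
#' Workhorse behind [fitGPR()]; exposed for direct use on arbitrary
#' regression problems (parameter-recovery studies, oracle comparisons).
#'
#' @param X n x p feature matrix.
#' @param y response vector.
#' @param direction label stored in the fit.
#' @param standardize standardize features and center the response
#'   (default TRUE).
#' @inheritParams fitGPR
#' @param fixed optional named list fixing hyperparameters (sigmaF, sigmaL,
#'   sigma2); fixed values are not optimized.
#' @return A \linkS4class{GPRFit}.
#' @export
fitGPRDirection <- function(X, y, direction = "x", standardize = TRUE,
                            maxit = 60L, nRestarts = 0L, restartSeed = 1L,
                            basis = c("constant", "none"), fixed = NULL) {
  basis <- match.arg(basis)
  stopifnot(nrow(X) == length(y))
  n <- length(y)

  if (standardize) {
    featCenter <- colMeans(X)
    featScale <- apply(X, 2L, stats::sd)
    featScale[featScale < 1e-12] <- 1
  } else {
    featCenter <- rep(0, ncol(X))
    featScale <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2L, featCenter), 2L, featScale, "/")
  yCenter <- if (basis == "constant") mean(y) else 0
  ys <- y - yCenter

  D2 <- sqDistMatrix(Xs)

  ## data-driven initialization
  sub <- capRows(n, 500L)
  meanDist <- mean(sqrt(sqDistMatrix(Xs[sub, , drop = FALSE])[
    upper.tri(diag(length(sub)))]))
  if (!is.finite(meanDist) || meanDist <= 0) meanDist <- 1
  sdY <- stats::sd(ys)
  if (!is.finite(sdY) || sdY <= 0) sdY <- 1e-3
  init <- log(c(sdY, meanDist, sqrt(0.1) * sdY))

  useBasis <- basis == "constant"
  objFull <- function(par, grad) {
    if (useBasis) gprObjective(par, ys, D2, grad = grad)
    else gprZeroBasis(par, ys, D2, grad = grad)
  }

  ## allow fixing hyperparameters (used by oracle tests)
  fixedPar <- c(sigmaF = NA_real_, sigmaL = NA_real_, sigma2 = NA_real_)
  if (!is.null(fixed)) for (nm in names(fixed)) fixedPar[nm] <- fixed[[nm]]
  fixMask <- !is.na(fixedPar)
  fixVals <- log(c(fixedPar["sigmaF"], fixedPar["sigmaL"],
                   sqrt(fixedPar["sigma2"])))
  expand <- function(parFree) {
    par <- init
    par[fixMask] <- fixVals[fixMask]
    par[!fixMask] <- parFree
    par
  }

  ll0 <- -objFull(expand(init[!fixMask]), grad = FALSE)$nll
  bestPar <- init[!fixMask]
  bestVal <- -ll0

  if (any(!fixMask)) {
    starts <- list(init[!fixMask])
    if (nRestarts > 0L) {
      set.seed(restartSeed)
      for (r in seq_len(nRestarts))
        starts[[r + 1L]] <- init[!fixMask] +
          stats::rnorm(sum(!fixMask), 0, 0.7)
    }
    for (st in starts) {
      opt <- try(stats::optim(
        st,
        fn = function(p) objFull(expand(p), grad = FALSE)$nll,
        gr = function(p) objFull(expand(p), grad = TRUE)$gradient[!fixMask],
        method = "L-BFGS-B", lower = -12, upper = 12,
        control = list(maxit = maxit)), silent = TRUE)
      if (!inherits(opt, "try-error") && is.finite(opt$value) &&
          opt$value < bestVal) {
        bestVal <- opt$value
        bestPar <- opt$par
      }
    }
  }

  par <- expand(bestPar)
  final <- objFull(par, grad = FALSE)
  hyp <- c(sigmaF = exp(par[1]), sigmaL = exp(par[2]), sigma2 = exp(2 * par[3]))
  new("GPRFit",
      direction = direction, hyp = hyp,
      beta = if (useBasis) final$beta else 0,
      yCenter = yCenter, featCenter = featCenter, featScale = featScale,
      X = Xs, y = ys, cholK = final$U, alpha = final$alpha,
      jitter = final$jitter, logLik = -final$nll, logLik0 = ll0)
}

## Zero-basis variant of the objective (beta = 0), for reference
## cross-checks where the comparison implementation has no explicit basis.
gprZeroBasis <- function(par, y, D2, grad = FALSE) {
  n <- length(y)
  sf2 <- exp(2 * par[1]); sl2 <- exp(2 * par[2]); s2 <- exp(2 * par[3])
  K <- sf2 * exp(-0.5 * D2 / sl2)
  cj <- cholWithJitter(K + diag(s2, n))
  U <- cj$U
  alpha <- cholSolve(U, y)
  ll <- -0.5 * sum(y * alpha) - 0.5 * n * log(2 * pi) - sum(log(diag(U)))
  if (!grad)
    return(list(nll = -ll, ll = ll, U = U, alpha = alpha, beta = 0,
                jitter = cj$jitter))
  Kinv <- chol2inv(U)
  A <- tcrossprod(alpha) - Kinv
  list(nll = -ll,
       gradient = -c(sum(A * K), 0.5 * sum(A * (K * (D2 / sl2))),
                     s2 * sum(diag(A))),
       ll = ll)
}

#' Posterior prediction from a single-direction GP fit
#'
#' Computes the posterior mean
#' \eqn{\mu = k_*^T (K+\sigma^2 I)^{-1} (F - H\beta) + H_*\beta} and
#' covariance \eqn{\Sigma = k_{**} - k_*^T (K+\sigma^2 I)^{-1} k_*}. The
#' reported variance is predictive by default (diag(\eqn{\Sigma}) plus the
#' noise variance); the 95% interval is \eqn{\mu \pm 1.96\sqrt{variance}}.
#'
#' @param fit a \linkS4class{GPRFit}.
#' @param newdata m x p feature matrix on the raw (unstandardized) scale.
#' @param includeNoise include the noise variance in the reported variance
#'   (predictive interval; set FALSE for the latent-function interval).
#' @param fullCov also return the full posterior covariance matrix.
#' @return List with `mean`, `variance`, `ci95Low`, `ci95High` (length-m
#'   vectors), and `cov` (m x m) when `fullCov = TRUE`.
#' @export
predictGPRDirection <- function(fit, newdata, includeNoise = TRUE,
                                fullCov = FALSE) {
  stopifnot(ncol(newdata) == ncol(fit@X))
  Xs <- sweep(sweep(newdata, 2L, fit@featCenter), 2L, fit@featScale, "/")
  sf <- fit@hyp[["sigmaF"]]; sl <- fit@hyp[["sigmaL"]]
  s2 <- fit@hyp[["sigma2"]]
  Kstar <- seKernelMatrix(fit@X, Xs, sf, sl)          # n x m
  mu <- drop(crossprod(Kstar, fit@alpha)) + fit@beta + fit@yCenter
  V <- backsolve(fit@cholK, Kstar, transpose = TRUE)  # n x m
  latentVar <- sf^2 - colSums(V^2)
  if (any(latentVar < -1e-8))
    stop("negative posterior variance beyond numerical tolerance")
  latentVar <- pmax(latentVar, 1e-12)
  variance <- latentVar + if (includeNoise) s2 else 0
  out <- list(mean = mu, variance = variance,
              ci95Low = mu - 1.96 * sqrt(variance),
              ci95High = mu + 1.96 * sqrt(variance))
  if (fullCov) {
    Kss <- seKernelMatrix(Xs, Xs, sf, sl)
    out$cov <- Kss - crossprod(V)
  }
  out
}

#' Predict GRFs with a fitted GPR model
#'
#' @param object a \linkS4class{GPRModel}.
#' @param newdata m x 12 sensor feature matrix.
#' @param includeNoise predictive (TRUE) vs latent (FALSE) variance.
#' @return List with matrices `mean`, `variance`, `ci95Low`, `ci95High`
#'   (m x fitted directions).
#' @export
setMethod("predict", "GPRModel", function(object, newdata,
                                          includeNoise = TRUE) {
  preds <- lapply(object@fits, predictGPRDirection, newdata = newdata,
                  includeNoise = includeNoise)
  collect <- function(fieldname)
    do.call(cbind, lapply(preds, `[[`, fieldname))
  out <- lapply(c(mean = "mean", variance = "variance",
                  ci95Low = "ci95Low", ci95High = "ci95High"), collect)
  for (i in seq_along(out)) colnames(out[[i]]) <- names(object@fits)
  out
})

#' Serialize a GPR model to JSON
#'
#' Writes hyperparameters, standardization constants and the training
#' arrays needed for prediction as a single JSON document.
#'
#' @param model a \linkS4class{GPRModel}.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGPRModel <- function(model, path) {
  fits <- lapply(model@fits, function(f) list(
    direction = f@direction, hyp = as.list(f@hyp), beta = f@beta,
    yCenter = f@yCenter, featCenter = f@featCenter, featScale = f@featScale,
    jitter = f@jitter, logLik = f@logLik, logLik0 = f@logLik0,
    X = f@X, y = f@y, alpha = f@alpha))
  jsonlite::write_json(list(type = "GPRModel", trainingN = model@trainingN,
                            fits = fits),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GPR model serialized by [writeGPRModel()]
#'
#' Rebuilds the Cholesky factorization from the stored training arrays.
#'
#' @param path JSON file path.
#' @return A \linkS4class{GPRModel}.
#' @export
readGPRModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fits <- lapply(obj$fits, function(f) {
    X <- as.matrix(f$X)
    hyp <- unlist(f$hyp)
    Kn <- seKernelMatrix(X, X, hyp[["sigmaF"]], hyp[["sigmaL"]]) +
      diag(hyp[["sigma2"]] + f$jitter, nrow(X))
    new("GPRFit", direction = f$direction, hyp = hyp, beta = f$beta,
        yCenter = f$yCenter, featCenter = as.numeric(f$featCenter),
        featScale = as.numeric(f$featScale), X = X, y = as.numeric(f$y),
        cholK = chol(Kn), alpha = as.numeric(f$alpha), jitter = f$jitter,
        logLik = f$logLik, logLik0 = f$logLik0)
  })
  names(fits) <- vapply(fits, function(f) f@direction, character(1))
  new("GPRModel", fits = fits, trainingN = as.integer(obj$trainingN))
}
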