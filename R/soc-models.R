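#' NIPALS partial least squares (single response)
#'
#' Mean-centred predictors and response, no predictor scaling. Returns the
#' loadings/weights of every extracted component so predictions can be made
#' with any truncation \code{1..ncomp}.
#'
#' @param X numeric matrix (samples x bands).
#' @param y numeric response vector.
#' @param ncomp number of components to extract.
#' @param tol component-extraction tolerance on the score sum of squares.
#' @return list with weights \code{W}, x-loadings \code{P}, y-loadings
#'   \code{q}, centres, and \code{ncomp} actually extracted.
#' @export
plsNipals <- function(X, y, ncomp, tol = 1e-12) {
  stopifnot(is.matrix(X), length(y) == nrow(X))
  xMean <- colMeans(X)
  yMean <- mean(y)
  E <- sweep(X, 2L, xMean)
  f <- y - yMean
  p <- ncol(X)
  ncomp <- min(ncomp, nrow(X) - 1L, p)
  W <- P <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  a <- 0L
  for (k in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    wn <- sqrt(sum(w^2))
    if (wn < tol) break
    w <- w / wn
    t_ <- drop(E %*% w)
    tt <- sum(t_^2)
    if (tt < tol) break
    pLoad <- drop(crossprod(E, t_)) / tt
    qk <- sum(f * t_) / tt
    E <- E - tcrossprod(t_, pLoad)
    f <- f - t_ * qk
    a <- k
    W[, k] <- w; P[, k] <- pLoad; q[k] <- qk
  }
  list(W = W[, seq_len(a), drop = FALSE], P = P[, seq_len(a), drop = FALSE],
       q = q[seq_len(a)], xMean = xMean, yMean = yMean, ncomp = a)
}

#' Predict from a NIPALS PLS fit
#' @param fit a \code{\link{plsNipals}} fit.
#' @param Xnew matrix of spectra.
#' @param ncomp truncation (default: all extracted components).
#' @return numeric vector of predictions.
#' @export
plsPredict <- function(fit, Xnew, ncomp = fit$ncomp) {
  ncomp <- min(ncomp, fit$ncomp)
  if (ncomp == 0L) return(rep(fit$yMean, nrow(Xnew)))
  W <- fit$W[, seq_len(ncomp), drop = FALSE]
  P <- fit$P[, seq_len(ncomp), drop = FALSE]
  q <- fit$q[seq_len(ncomp)]
  B <- W %*% solve(crossprod(P, W), q)
  drop(sweep(Xnew, 2L, fit$xMean) %*% B) + fit$yMean
}

trainMatrix <- function(cal) {
  info <- calInfo(cal)
  keep <- info$role == "train"
  list(X = calSpectra(cal)[keep, , drop = FALSE], y = info$soc[keep],
       info = info[keep, , drop = FALSE])
}

newFittedModel <- function(algorithm, fit, hyper, cal, scaling = NULL,
                           seed = 1L) {
  new("FittedSOCModel", algorithm = algorithm, fit = fit,
      hyperparameters = hyper, treatment = treatment(cal),
      socMin = unname(calibrationLimits(cal)["socMin"]),
      socMax = unname(calibrationLimits(cal)["socMax"]),
      scaling = scaling, biasCorrection = NULL,
      wavelengths = wavelengths(cal), seed = as.integer(seed))
}

#' Fit a PLS SOC model with cross-validated component selection
#'
#' Components \code{1..maxComponents} are scored by k-fold cross-validated
#' mean squared error of prediction on the training samples; the minimising
#' count is selected (ties go to the smaller count) and the final model is
#' refit on all training samples.
#'
#' @param cal a \linkS4class{CalibrationSet}.
#' @param maxComponents largest component count tried (default 20; capped
#'   at the data rank with a warning).
#' @param cvFolds number of CV folds (default 5).
#' @param forcedComponents optionally bypass selection with a fixed count
#'   (the CV-optimal count is still reported).
#' @param seed integer seed (fold assignment).
#' @return a \linkS4class{FittedSOCModel}.
#' @export
fitPLS <- function(cal, maxComponents = 20L, cvFolds = 5L,
                   forcedComponents = NULL, seed = 1L) {
  tr <- trainMatrix(cal)
  n <- nrow(tr$X)
  if (n < cvFolds) stop("fewer training samples than folds")
  cap <- min(maxComponents, n - ceiling(n / cvFolds) - 1L, ncol(tr$X))
  if (cap < maxComponents)
    warning("maxComponents capped at ", cap, " by the training-set rank")
  folds <- withSeed(substreamSeed(seed, "pls_folds"),
                    sample(rep(seq_len(cvFolds), length.out = n)))
  sse <- numeric(cap)
  for (kf in seq_len(cvFolds)) {
    hold <- folds == kf
    fit <- plsNipals(tr$X[!hold, , drop = FALSE], tr$y[!hold], cap)
    for (a in seq_len(cap)) {
      pred <- plsPredict(fit, tr$X[hold, , drop = FALSE], a)
      sse[a] <- sse[a] + sum((pred - tr$y[hold])^2)
    }
  }
  msep <- sse / n
  nOpt <- which.min(msep)  # first minimum = fewest components on ties
  nUse <- if (is.null(forcedComponents)) nOpt else
    min(as.integer(forcedComponents), cap)
  fit <- plsNipals(tr$X, tr$y, nUse)
  newFittedModel("pls", fit,
                 list(nComponents = fit$ncomp, cvOptimalComponents = nOpt,
                      cvMSEP = msep, cvFolds = cvFolds), cal, seed = seed)
}

#' Fit a random forest SOC model
#'
#' 200 regression trees by default, each grown on a random 33\% draw of the
#' training samples without replacement (the remaining 67\% serve as the
#' out-of-bag evaluation), \code{mtry} candidate predictors per split
#' (default \code{round(sqrt(bands))} = 14 for 186 bands) and terminal
#' nodes of minimum size 1 (so any node with at least 2 cases may split).
#'
#' @param cal a \linkS4class{CalibrationSet}.
#' @param nTrees number of trees.
#' @param sampleFraction per-tree training fraction (without replacement).
#' @param mtry candidate predictors per split.
#' @param minLeaf minimum terminal-node size.
#' @param seed integer seed.
#' @return a \linkS4class{FittedSOCModel}; out-of-bag RMSE is reported in
#'   the hyperparameters.
#' @export
fitRF <- function(cal, nTrees = 200L, sampleFraction = 0.33,
                  mtry = NULL, minLeaf = 1L, seed = 1L) {
  tr <- trainMatrix(cal)
  if (length(unique(tr$y)) < 2L)
    stop("training SOC values are constant; nothing to learn")
  if (is.null(mtry)) mtry <- max(1L, round(sqrt(ncol(tr$X))))
  sampsize <- max(2L, round(sampleFraction * nrow(tr$X)))
  fit <- withSeed(substreamSeed(seed, "rf"),
    randomForest::randomForest(x = tr$X, y = tr$y, ntree = nTrees,
      mtry = mtry, replace = FALSE, sampsize = sampsize,
      nodesize = minLeaf))
  oobRMSE <- sqrt(mean((fit$predicted - tr$y)^2))
  newFittedModel("rf", fit,
                 list(nTrees = nTrees, mtry = mtry,
                      sampleFraction = sampleFraction,
                      oobRMSE = oobRMSE, trainRange = range(tr$y)),
                 cal, seed = seed)
}

#' Default SVM hyperparameter grid
#'
#' Brackets the regime where radial-kernel epsilon-regression on unit-scaled
#' SNV spectra typically optimises (gamma ~ 1e-2, cost ~ 8, epsilon ~ 0.1).
#' @return data.frame of gamma/cost/epsilon combinations.
#' @export
defaultSVMGrid <- function() {
  expand.grid(gamma = c(1e-3, 1e-2, 1e-1, 1),
              cost = c(1, 2, 4, 8, 16, 32),
              epsilon = c(0.05, 0.1, 0.2))
}

#' Fit a support-vector SOC model (epsilon-regression, radial kernel)
#'
#' Predictors are scaled per band to the unit interval (the stored scaling
#' is reapplied at prediction time). The grid is scored both by k-fold
#' cross-validated RMSE and by bootstrap RMSE (train on a random third,
#' evaluate on the remaining two thirds); CV RMSE decides the selection.
#' The response is regressed unscaled (mg/g), so epsilon is in SOC units.
#'
#' @param cal a \linkS4class{CalibrationSet} (typically SNV spectra).
#' @param grid data.frame with columns gamma, cost, epsilon; a single-row
#'   grid is allowed (selection is then trivial).
#' @param cvFolds number of CV folds (default 10).
#' @param bootstrapReps bootstrap repetitions (default 25).
#' @param seed integer seed.
#' @return a \linkS4class{FittedSOCModel}; the chosen parameters, the
#'   support-vector count and both score tables are in the hyperparameters.
#' @export
fitSVM <- function(cal, grid = defaultSVMGrid(), cvFolds = 10L,
                   bootstrapReps = 25L, seed = 1L) {
  stopifnot(nrow(grid) >= 1L,
            all(c("gamma", "cost", "epsilon") %in% names(grid)))
  tr <- trainMatrix(cal)
  scaling <- scaleToUnitInterval(tr$X)
  X <- scaling$scaled
  y <- tr$y
  n <- nrow(X)
  folds <- withSeed(substreamSeed(seed, "svm_folds"),
                    sample(rep(seq_len(cvFolds), length.out = n)))
  bootIdx <- withSeed(substreamSeed(seed, "svm_boot"),
                      lapply(seq_len(bootstrapReps), function(i)
                        sample.int(n, max(2L, floor(n / 3)))))
  # an epsilon tube wider than every residual leaves no support vectors;
  # the fit degenerates to the constant mean predictor
  svmFit <- function(Xt, yt, par) tryCatch(
    e1071::svm(x = Xt, y = yt, type = "eps-regression", kernel = "radial",
               gamma = par$gamma, cost = par$cost, epsilon = par$epsilon,
               scale = FALSE),
    error = function(e) structure(list(mu = mean(yt), SV = Xt[0, , drop = FALSE]),
                                  class = "svmConstant"))
  svmPred <- function(m, X) if (inherits(m, "svmConstant"))
    rep(m$mu, nrow(X)) else stats::predict(m, X)
  cvRMSE <- bootRMSE <- numeric(nrow(grid))
  for (gIdx in seq_len(nrow(grid))) {
    par <- grid[gIdx, ]
    sse <- 0
    for (kf in seq_len(cvFolds)) {
      hold <- folds == kf
      if (!any(hold) || sum(!hold) < 2L) next
      m <- svmFit(X[!hold, , drop = FALSE], y[!hold], par)
      sse <- sse + sum((svmPred(m, X[hold, , drop = FALSE]) -
                          y[hold])^2)
    }
    cvRMSE[gIdx] <- sqrt(sse / n)
    bse <- vapply(bootIdx, function(idx) {
      m <- svmFit(X[idx, , drop = FALSE], y[idx], par)
      mean((svmPred(m, X[-idx, , drop = FALSE]) - y[-idx])^2)
    }, numeric(1))
    bootRMSE[gIdx] <- sqrt(mean(bse))
  }
  best <- which.min(cvRMSE)
  par <- grid[best, ]
  fit <- svmFit(X, y, par)
  newFittedModel("svm", fit,
                 list(gamma = par$gamma, cost = par$cost,
                      epsilon = par$epsilon,
                      nSupportVectors = nrow(fit$SV),
                      cvRMSE = cvRMSE[best], bootstrapRMSE = bootRMSE[best],
                      grid = cbind(grid, cvRMSE = cvRMSE,
                                   bootstrapRMSE = bootRMSE)),
                 cal, scaling = scaling, seed = seed)
}

#' Predict SOC for a matrix of spectra
#'
#' @param model a \linkS4class{FittedSOCModel}.
#' @param spectra matrix (samples x bands) in the model's treatment.
#' @return numeric vector of SOC predictions (mg/g), unconstrained.
#' @export
predictSpectra <- function(model, spectra) {
  stopifnot(is(model, "FittedSOCModel"), is.matrix(spectra))
  if (ncol(spectra) != length(wavelengths(model)))
    stop("band count mismatch: model expects ", length(wavelengths(model)),
         " bands, spectra have ", ncol(spectra))
  switch(algorithm(model),
    pls = plsPredict(model@fit, spectra),
    rf = unname(stats::predict(model@fit, spectra)),
    svm = {
      scaled <- applyUnitScaling(spectra, model@scaling)
      if (inherits(model@fit, "svmConstant")) rep(model@fit$mu, nrow(scaled))
      else unname(stats::predict(model@fit, scaled))
    })
}

#' Predict a per-pixel SOC map
#'
#' Applies a fitted model to every unmasked pixel of a cube whose spectral
#' treatment matches the model's. Masked pixels are \code{NA}. The raw
#' (unconstrained, uncorrected) predictions are preserved in the map's
#' \code{rawValues} whatever adjustments follow.
#'
#' @param model a \linkS4class{FittedSOCModel}.
#' @param cube a \linkS4class{SpectralCube}.
#' @return a \linkS4class{SOCMap}.
#' @export
predictMap <- function(model, cube) {
  stopifnot(is(model, "FittedSOCModel"), is(cube, "SpectralCube"))
  if (treatment(cube) != treatment(model))
    stop("cube treatment '", treatment(cube),
         "' does not match model treatment '", treatment(model), "'")
  vals <- cubeValues(cube)
  d <- dim(vals)
  mask <- soilMask(cube)
  flat <- matrix(vals, d[1L] * d[2L], d[3L])
  idx <- which(as.vector(mask))
  pred <- predictSpectra(model, flat[idx, , drop = FALSE])
  out <- matrix(NA_real_, d[1L], d[2L])
  out[idx] <- pred
  SOCMap(out, mask = mask, pixelSize = pixelSize(cube),
         depthOrigin = depthOrigin(cube),
         modelInfo = list(algorithm = algorithm(model),
                          treatment = treatment(model),
                          hyperparameters = hyperparameters(model),
                          socMin = model@socMin, socMax = model@socMax))
}

#' Constrain predictions to the calibration range
#'
#' Values below zero are replaced by the calibration minimum and values
#' above the calibration maximum by the calibration maximum. Values in
#' \code{[0, socMin)} are deliberately left unchanged: only negatives are
#' raised.
#'
#' @param map a \linkS4class{SOCMap}.
#' @param socMin,socMax calibration limits (mg/g); default: the limits of
#'   the model that produced the map.
#' @return the constrained map (idempotent).
#' @export
constrainPredictions <- function(map, socMin = NULL, socMax = NULL) {
  stopifnot(is(map, "SOCMap"))
  if (is.null(socMin)) socMin <- map@modelInfo$socMin
  if (is.null(socMax)) socMax <- map@modelInfo$socMax
  stopifnot(is.finite(socMin), is.finite(socMax), socMin < socMax)
  v <- socValues(map)
  v[!is.na(v) & v < 0] <- socMin
  v[!is.na(v) & v > socMax] <- socMax
  SOCMap(v, mask = soilMask(map), pixelSize = pixelSize(map),
         depthOrigin = depthOrigin(map), rawValues = rawValues(map),
         adjustments = unique(c(adjustments(map), "constrained")),
         modelInfo = map@modelInfo)
}

#' Estimate a depth-stratified bias correction
#'
#' Tree-ensemble SOC predictions regress toward the node mean, so
#' carbon-rich topsoil is underestimated and carbon-poor subsoil
#' overestimated. The correction is the negated mean residual
#' (predicted - measured) of the validation samples per horizon. The
#' residual correlation with horizontal position is reported as a
#' diagnostic (it is expected to be ~0; position across the core carries no
#' information about bias).
#'
#' @param model a \linkS4class{FittedSOCModel}.
#' @param cal the \linkS4class{CalibrationSet} whose validate-role samples
#'   carry depth, column and horizon labels.
#' @param horizonBoundaryCm boundary depth (cm) used when applying the
#'   correction (identified visually/from PCA on real cores; the generator
#'   truth on synthetic ones).
#' @param minPerHorizon smallest acceptable validation count per horizon.
#' @return a \linkS4class{BiasCorrection}.
#' @export
estimateBiasCorrection <- function(model, cal, horizonBoundaryCm = 30,
                                   minPerHorizon = 3L) {
  info <- calInfo(cal)
  keep <- info$role == "validate"
  if (!any(keep)) stop("calibration set has no validation samples")
  info <- info[keep, , drop = FALSE]
  pred <- predictSpectra(model, calSpectra(cal)[keep, , drop = FALSE])
  resid <- pred - info$soc
  for (h in c("topsoil", "subsoil"))
    if (sum(info$horizon == h) < minPerHorizon)
      stop("fewer than ", minPerHorizon, " validation samples in the ", h)
  offT <- -mean(resid[info$horizon == "topsoil"])
  offS <- -mean(resid[info$horizon == "subsoil"])
  colCor <- if (stats::sd(info$column) > 0 && stats::sd(resid) > 0)
    stats::cor(resid, info$column) else 0
  BiasCorrection(offT, offS, horizonBoundaryCm,
                 diagnostics = list(columnCorrelation = colCor,
                                    n = nrow(info)))
}

#' Apply a depth-stratified bias correction to a map
#'
#' Rows above the horizon boundary are shifted by the topsoil offset, rows
#' below by the subsoil offset. No clipping is applied afterwards, so the
#' corrected map may extend slightly past the calibration limits.
#'
#' @param map a \linkS4class{SOCMap}.
#' @param bc a \linkS4class{BiasCorrection}.
#' @return the corrected map.
#' @export
applyBiasCorrection <- function(map, bc) {
  stopifnot(is(map, "SOCMap"), is(bc, "BiasCorrection"))
  depths <- rowDepths(map)
  v <- socValues(map)
  off <- ifelse(depths < bc@horizonBoundary, bc@topsoilOffset,
                bc@subsoilOffset)
  v <- v + matrix(off, nrow(v), ncol(v))
  SOCMap(v, mask = soilMask(map), pixelSize = pixelSize(map),
         depthOrigin = depthOrigin(map), rawValues = rawValues(map),
         adjustments = unique(c(adjustments(map), "bias_corrected")),
         modelInfo = c(map@modelInfo,
                       list(biasOffsets = biasOffsets(bc),
                            horizonBoundary = bc@horizonBoundary)))
}
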