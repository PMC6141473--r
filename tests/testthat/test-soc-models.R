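makeCal <- function(X, y, treatment = "snv", valX = X, valY = y) {
  n <- nrow(X); m <- nrow(valX)
  info <- data.frame(
    roiId = paste0("r", c(seq_len(n), seq_len(m))),
    statistic = "mean",
    subsetId = c(rep("r1", n), rep("full", m)),
    role = c(rep("train", n), rep("validate", m)),
    soc = c(y, valY),
    depthCm = 50, column = 1, horizon = "subsoil")
  new("CalibrationSet", spectra = rbind(X, valX), info = info,
      treatment = treatment, socMin = min(y), socMax = max(y),
      wavelengths = seq_len(ncol(X)))
}

test_that("PLS recovers an exactly linear response and permutes cleanly", {
  set.seed(31)
  X <- matrix(rnorm(40 * 12), 40, 12)
  w <- rnorm(12)
  y <- drop(X %*% w) + 5
  cal <- makeCal(X, y)
  fit <- fitPLS(cal, maxComponents = 10, seed = 1)
  pred <- predictSpectra(fit, X)
  r2 <- 1 - sum((pred - y)^2) / sum((y - mean(y))^2)
  expect_gte(r2, 0.999)
  # permuting band order of train and prediction spectra changes nothing
  perm <- sample(12)
  calP <- makeCal(X[, perm], y)
  fitP <- fitPLS(calP, maxComponents = 10, seed = 1)
  expect_equal(predictSpectra(fitP, X[, perm]), pred, tolerance = 1e-8)
})

test_that("one-component NIPALS equals the rank-1 deflation oracle", {
  set.seed(8)
  X <- matrix(rnorm(5 * 7), 5, 7)
  y <- rnorm(5)
  fit <- plsNipals(X, y, 1)
  Xnew <- matrix(rnorm(3 * 7), 3, 7)
  expect_equal(plsPredict(fit, Xnew, 1),
               bruteOneComponentPLS(X, y, Xnew), tolerance = 1e-10)
})

test_that("PLS component selection minimises CV MSEP with parsimony ties", {
  set.seed(13)
  X <- matrix(rnorm(60 * 15), 60, 15)
  y <- drop(X[, 1:3] %*% c(1, -2, 0.5)) + rnorm(60, sd = 0.1)
  cal <- makeCal(X, y)
  fit <- fitPLS(cal, maxComponents = 10, cvFolds = 5, seed = 2)
  hp <- hyperparameters(fit)
  expect_identical(hp$nComponents, which.min(hp$cvMSEP))
  forced <- fitPLS(cal, maxComponents = 10, forcedComponents = 7, seed = 2)
  expect_identical(hyperparameters(forced)$nComponents, 7L)
  expect_identical(hyperparameters(forced)$cvOptimalComponents,
                   hp$cvOptimalComponents)
})

test_that("random forest predictions stay inside the training SOC range", {
  set.seed(41)
  X <- matrix(rnorm(50 * 10), 50, 10)
  y <- runif(50, 2, 16)
  cal <- makeCal(X, y)
  fit <- fitRF(cal, seed = 3)
  far <- matrix(rnorm(30 * 10, mean = 10), 30, 10)  # way out of domain
  pred <- predictSpectra(fit, far)
  expect_true(all(pred >= min(y) & pred <= max(y)))
  # constant response gives constant predictions
  calC <- makeCal(X, c(rep(5, 49), 5.0000001))
  fitC <- suppressWarnings(fitRF(calC, seed = 3))  # rF notes the flat response
  expect_equal(unique(round(predictSpectra(fitC, far), 5)), 5)
  # a fully constant response cannot even form a valid calibration set
  expect_error(makeCal(X, rep(5, 50)), "degenerate")
})

test_that("RF beats PLS on SNV spectra of the nonlinear forward model", {
  wins <- 0L
  diffs <- numeric(0)
  for (s in 1:10) {
    pc <- preparedCore(seed = 100 + s)
    rois <- selectROIsAuto(pc$nr, socField(pc$truth), n = 30,
                           seed = 100 + s)
    cal <- buildCalibrationSet(rois, list(core1 = pc$snv), seed = 100 + s)
    d <- validationRMSE(fitPLS(cal, seed = s), cal) -
      validationRMSE(fitRF(cal, seed = s), cal)
    diffs <- c(diffs, d)
    if (d > 0) wins <- wins + 1L
  }
  expect_gt(mean(diffs), 0)
  expect_gte(wins, 7L)
})

test_that("SVM honours a single-point grid and the epsilon-tube limit", {
  set.seed(17)
  X <- matrix(runif(40 * 8), 40, 8)
  y <- runif(40, 2, 10)
  cal <- makeCal(X, y)
  fit <- fitSVM(cal, grid = singlePointSVMGrid(), cvFolds = 5,
                bootstrapReps = 5, seed = 1)
  hp <- hyperparameters(fit)
  expect_identical(hp$gamma, 0.01)
  expect_identical(hp$cost, 8)
  expect_identical(hp$epsilon, 0.1)
  expect_gt(hp$nSupportVectors, 0)
  # epsilon wider than the response range: all residuals inside the tube
  wide <- fitSVM(cal, grid = data.frame(gamma = 0.01, cost = 8,
                                        epsilon = 20),
                 cvFolds = 5, bootstrapReps = 3, seed = 1)
  predW <- predictSpectra(wide, X)
  expect_lt(diff(range(predW)), 0.5)
  # determinism at fixed seed and folds
  fit2 <- fitSVM(cal, grid = singlePointSVMGrid(), cvFolds = 5,
                 bootstrapReps = 5, seed = 1)
  expect_identical(hyperparameters(fit2)$cvRMSE, hp$cvRMSE)
})

test_that("predictMap equals the pixel loop and respects mask/treatment", {
  pc <- preparedCore(seed = 7)
  rois <- selectROIsAuto(pc$nr, socField(pc$truth), n = 15, seed = 7)
  cal <- buildCalibrationSet(rois, list(core1 = pc$snv), seed = 7)
  fit <- fitRF(cal, nTrees = 50, seed = 7)
  map <- predictMap(fit, pc$snv)
  vals <- cubeValues(pc$snv)
  mask <- soilMask(pc$snv)
  idx <- which(mask, arr.ind = TRUE)
  pick <- idx[seq(1, nrow(idx), length.out = 25), , drop = FALSE]
  for (k in seq_len(nrow(pick))) {
    s <- matrix(vals[pick[k, 1], pick[k, 2], ], 1)
    expect_equal(socValues(map)[pick[k, 1], pick[k, 2]],
                 predictSpectra(fit, s), tolerance = 1e-10)
  }
  expect_true(all(is.na(socValues(map)[!mask])))
  expect_error(predictMap(fit, pc$nr), "treatment")
  small <- tinyCube(array(0.5, c(2, 2, 3)), treatment = "snv")
  expect_error(predictMap(fit, small), "band count")
})

test_that("calibration-range constraint matches the printed worked example", {
  m <- matrix(c(-187, 562, 5.0, 0.8, NA, 3.2), 2, 3)
  map <- SOCMap(m, mask = !is.na(m), pixelSize = 53,
                modelInfo = list(socMin = 1.6, socMax = 15.5))
  con <- constrainPredictions(map)
  expect_equal(socValues(con)[1, 1], 1.6)   # negative -> calibration minimum
  expect_equal(socValues(con)[2, 1], 15.5)  # above range -> maximum
  expect_equal(socValues(con)[1, 2], 5.0)   # in range unchanged
  expect_equal(socValues(con)[2, 2], 0.8)   # [0, socMin) NOT raised
  con2 <- constrainPredictions(con)
  expect_equal(socValues(con2), socValues(con))  # idempotent
  expect_identical(rawValues(con), m)            # raw preserved
  expect_true("constrained" %in% adjustments(con))
})

test_that("bias offsets are recovered from residuals with known means", {
  # a model predicting a constant 10 lets us plant residual group means
  p <- 6L
  fakeFit <- list(W = matrix(0, p, 0), P = matrix(0, p, 0),
                  q = numeric(0), xMean = rep(0, p), yMean = 10,
                  ncomp = 0L)
  set.seed(55)
  nPer <- 200L
  socTop <- rnorm(nPer, mean = 10 - 0.8, sd = 0.5)  # resid mean +0.8
  socSub <- rnorm(nPer, mean = 10 + 0.4, sd = 0.5)  # resid mean -0.4
  info <- data.frame(
    roiId = paste0("r", seq_len(2 * nPer)), statistic = "mean",
    subsetId = "full", role = "validate", soc = c(socTop, socSub),
    depthCm = rep(c(10, 60), each = nPer),
    column = runif(2 * nPer, 1, 24),
    horizon = rep(c("topsoil", "subsoil"), each = nPer))
  cal <- new("CalibrationSet",
             spectra = matrix(rnorm(2 * nPer * p), 2 * nPer, p),
             info = info, treatment = "snv", socMin = 1, socMax = 16,
             wavelengths = seq_len(p))
  model <- new("FittedSOCModel", algorithm = "pls", fit = fakeFit,
               hyperparameters = list(), treatment = "snv", socMin = 1,
               socMax = 16, scaling = NULL, biasCorrection = NULL,
               wavelengths = seq_len(p), seed = 1L)
  bc <- estimateBiasCorrection(model, cal, horizonBoundaryCm = 30)
  se <- 0.5 / sqrt(nPer)
  off <- biasOffsets(bc)
  expect_lt(abs(off["topsoil"] - (-0.8)), 4 * se)
  expect_lt(abs(off["subsoil"] - 0.4), 4 * se)
  expect_lt(abs(bc@diagnostics$columnCorrelation), 2 / sqrt(nPer))
})

test_that("bias correction applies the printed worked equations", {
  m <- matrix(c(7, 3), 2, 1)
  map <- SOCMap(m, pixelSize = 3e5, modelInfo = list())  # rows at 15, 45 cm
  bc <- BiasCorrection(1.5, -1.5, horizonBoundary = 30)
  out <- applyBiasCorrection(map, bc)
  expect_equal(socValues(out)[1, 1], 8.5)
  expect_equal(socValues(out)[2, 1], 1.5)
  shift <- socValues(out) - socValues(map)
  expect_true(all(shift %in% c(1.5, -1.5)))
  zero <- applyBiasCorrection(map, BiasCorrection(0, 0, 30))
  expect_equal(socValues(zero), socValues(map))
  expect_identical(rawValues(out), m)
})
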