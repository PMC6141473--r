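test_that("target normalization handles identity, linearity and errors", {
  vals <- array(0.5, c(2, 3, 4))
  wl <- c(400, 600, 800, 990)
  cube <- SpectralCube(vals, wl, 2500)
  target <- ReflectanceTarget(matrix(0.5, 3, 4), 0.5)
  out <- normalizeToTarget(cube, target)
  expect_equal(unique(as.vector(cubeValues(out))), 0.5)
  expect_identical(treatment(out), "normalized_reflectance")
  cube2 <- SpectralCube(array(0.25, c(2, 3, 4)), wl, 2500)
  expect_equal(unique(as.vector(cubeValues(
    normalizeToTarget(cube2, target)))), 0.25)
  # linear in I_sample: doubling intensity doubles reflectance
  cube3 <- SpectralCube(2 * vals, wl, 2500)
  expect_equal(cubeValues(normalizeToTarget(cube3, target)),
               2 * cubeValues(out), tolerance = 1e-12)
  badT <- matrix(0.5, 3, 4); badT[2, 3] <- 0
  # constructor itself refuses a non-positive target
  expect_error(ReflectanceTarget(badT, 0.5), "strictly positive")
  # and normalization identifies band/column if handed one built around it
  tgt <- ReflectanceTarget(matrix(0.5, 3, 4), 0.5)
  tgt@intensity[2, 3] <- 0
  expect_error(normalizeToTarget(cube, tgt), "column 2, band 3")
  expect_error(normalizeToTarget(out, target), "raw-intensity")
})

test_that("normalization cancels the illumination gradient", {
  cfg <- syntheticCoreConfig(seed = 4, scatterGainSD = 0,
    scatterOffsetSD = 0, bandNoiseSD = 0, crackFraction = 0,
    illuminationGradientAmplitude = 0.2, ploughCV = 0,
    subsoilCVAtBottom = 0, biopores = noBiopores())
  fld <- generateSOCField(cfg)$socField
  rc <- renderCube(fld, cfg)
  b <- 10
  rawCols <- colMeans(cubeValues(rc$cube)[1:50, , b])
  expect_gt(diff(range(rawCols)) / mean(rawCols), 0.1)
  norm <- normalizeToTarget(rc$cube, rc$target)
  expect_equal(cubeValues(norm), trueReflectance(fld, cfg),
               tolerance = 1e-12)
})

test_that("masking recovers planted non-soil pixels and is monotone", {
  tc <- simulateCore(syntheticCoreConfig(seed = 8, crackFraction = 0.02,
                                         backgroundCols = 2L))
  norm <- normalizeToTarget(rawCube(tc), reflectanceTarget(tc))
  masked <- maskNonSoil(norm)
  agreement <- mean(soilMask(masked) == !nonSoilMaskTruth(tc))
  expect_gte(agreement, 0.99)
  # vacuous thresholds change nothing
  expect_identical(soilMask(maskNonSoil(norm, 0, c(0, Inf))),
                   soilMask(norm))
  # spectral values are untouched by masking
  expect_identical(cubeValues(masked), cubeValues(norm))
  # raising the NIR threshold never unmasks a pixel
  tighter <- maskNonSoil(norm, upperBandThreshold = 0.3)
  expect_true(all(which(soilMask(tighter)) %in% which(soilMask(masked))))
  expect_warning(maskNonSoil(norm, upperBandThreshold = 10), "100%")
})

test_that("a clean all-soil cube is not masked under default thresholds", {
  tc <- simulateCore(syntheticCoreConfig(seed = 12, crackFraction = 0))
  norm <- normalizeToTarget(rawCube(tc), reflectanceTarget(tc))
  masked <- maskNonSoil(norm)
  expect_lt(1 - mean(soilMask(masked)), 0.01)
})

test_that("SNV matches the hand computation and its invariances", {
  expect_equal(snvRows(rbind(c(1, 2, 3)))[1, ], c(-1, 0, 1),
               tolerance = 1e-12)
  set.seed(99)
  s <- runif(20)
  expect_equal(snvRows(rbind(2 * s + 7))[1, ], snvRows(rbind(s))[1, ],
               tolerance = 1e-10)
  # cube interface: every unmasked pixel ends with mean 0, sd 1
  pc <- preparedCore(seed = 3)
  vals <- cubeValues(pc$snv)
  d <- dim(vals)
  mat <- matrix(vals, d[1] * d[2], d[3])[as.vector(soilMask(pc$snv)), ]
  expect_lt(max(abs(rowMeans(mat))), 1e-10)
  expect_lt(max(abs(apply(mat, 1, sd) - 1)), 1e-10)
})

test_that("flat-spectrum pixels are masked and counted, never divided", {
  vals <- array(runif(2 * 2 * 5), c(2, 2, 5))
  vals[1, 1, ] <- 0.4  # constant spectrum
  cube <- SpectralCube(vals, 1:5 * 100 + 300, 2500,
                       treatment = "normalized_reflectance")
  out <- snvTransform(cube)
  expect_false(soilMask(out)[1, 1])
  expect_identical(out@metadata$flatPixelCount, 1L)
  expect_true(all(is.finite(cubeValues(out)[2, , ])))
})

test_that("unit-interval scaling follows the stored-parameter contract", {
  m <- rbind(c(2, 10), c(4, 30))
  sc <- scaleToUnitInterval(m)
  expect_equal(sc$scaled[, 1], c(0, 1))
  # stored scaling applied to new data may leave [0, 1]; no clipping
  expect_equal(applyUnitScaling(rbind(c(5, 20)), sc)[1, 1], 1.5)
  set.seed(7)
  x <- matrix(rnorm(60), 10, 6)
  sc2 <- scaleToUnitInterval(x)
  expect_equal(unscaleFromUnitInterval(sc2$scaled, sc2), x,
               tolerance = 1e-12)
  const <- cbind(rnorm(5), rep(3, 5))
  sc3 <- scaleToUnitInterval(const)
  expect_identical(sc3$constantBands, 2L)
  expect_equal(unique(sc3$scaled[, 2]), 0.5)
})

test_that("PCA rendering: rank-1 variance, ordering, horizon separation", {
  # pixels varying along a single spectral direction
  base <- seq(0.2, 0.6, length.out = 8)
  dir <- sin(seq_len(8))
  vals <- array(0, c(5, 4, 8))
  set.seed(1)
  amp <- matrix(rnorm(20), 5, 4)
  for (b in 1:8) vals[, , b] <- base[b] + amp * dir[b]
  cube <- tinyCube(vals, wl = seq(400, 990, length.out = 8))
  pr <- pcaRGB(cube, nComponents = 3)
  expect_gte(pr$explainedVariance[1], 0.999)
  expect_true(all(diff(pr$explainedVariance) <= 1e-12))
  # full-rank scores reconstruct the centred data
  prAll <- pcaRGB(cube, nComponents = 8)
  mat <- matrix(vals, 20, 8)
  recon <- prAll$scores %*% t(prAll$loadings)
  expect_equal(recon, sweep(mat, 2, colMeans(mat)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # sign convention: the largest-magnitude loading element is positive
  for (k in 1:3) {
    lk <- pr$loadings[, k]
    expect_gt(lk[which.max(abs(lk))], 0)
  }
  # synthetic core: first-component scores separate plough from subsoil
  pc <- preparedCore(seed = 2)
  pr2 <- pcaRGB(pc$nr)
  sc1 <- matrix(NA_real_, nrow(soilMask(pc$nr)), ncol(soilMask(pc$nr)))
  sc1[soilMask(pc$nr)] <- pr2$scores[, 1]
  topRows <- rowDepths(pc$nr) < 30
  tt <- t.test(sc1[topRows, ], sc1[!topRows, ])
  expect_lt(tt$p.value, 1e-6)
  expect_error(pcaRGB(rawCube(pc$truth)), "normalized")
})
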