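test_that("fixed seed gives a bit-identical core; seeds differ", {
  a <- simulateCore(syntheticCoreConfig(seed = 42))
  b <- simulateCore(syntheticCoreConfig(seed = 42))
  expect_identical(socField(a), socField(b))
  expect_identical(cubeValues(rawCube(a)), cubeValues(rawCube(b)))
  expect_identical(bulkTruth(a), bulkTruth(b))
  c_ <- simulateCore(syntheticCoreConfig(seed = 43))
  expect_false(identical(socField(a), socField(c_)))
})

test_that("plough-horizon moments match the configured mean and CV", {
  cfg <- syntheticCoreConfig(seed = 5, biopores = noBiopores())
  fld <- generateSOCField(cfg)$socField
  ploughRows <- seq_len(floor(30 / 100 * nrow(fld)))
  top <- fld[ploughRows, ]
  expect_lt(abs(mean(top) - 9) / 9, 0.02)
  cv <- sd(top) / mean(top)
  expect_lt(abs(cv - 0.2) / 0.2, 0.15)
})

test_that("zero-CV config reproduces the deterministic depth profile", {
  cfg <- syntheticCoreConfig(seed = 1, ploughCV = 0, subsoilCVAtBottom = 0,
                             biopores = noBiopores())
  fld <- generateSOCField(cfg)$socField
  prof <- truthDepthProfile(cfg)
  expect_equal(fld, matrix(prof$mean, nrow(fld), ncol(fld)),
               tolerance = 1e-12)
})

test_that("noise-free depth-mean profile is non-increasing below the plough", {
  prof <- truthDepthProfile(syntheticCoreConfig())
  sub <- prof[prof$depth >= 30, ]
  expect_true(all(diff(sub$mean) <= 1e-12))
})

test_that("biopore SOC equals the enrichment factor times the local matrix", {
  # one biopore over 60-80 cm, enrichment 4; local matrix mean ~4 mg/g
  bp <- data.frame(topDepth = 60, bottomDepth = 80, center = 3,
                   width = 8, enrichment = 4)
  cfg <- syntheticCoreConfig(seed = 9, biopores = bp)
  g <- generateSOCField(cfg)
  core <- g$bioporeLabels == 1L
  expect_gt(sum(core), 0)
  prof <- truthDepthProfile(cfg)
  localMean <- mean(prof$mean[rowSums(core) > 0])
  expect_equal(mean(g$socField[core]), 4 * localMean, tolerance = 0.02)
  # against the matrix within 1 cm of the footprint, excluding it
  ring <- which(core, arr.ind = TRUE)
  rPx <- round(1e4 / cfg@pixelSize)
  near <- matrix(FALSE, nrow(g$socField), ncol(g$socField))
  for (k in seq_len(nrow(ring))) {
    rows <- max(1, ring[k, 1] - rPx):min(nrow(near), ring[k, 1] + rPx)
    cols <- max(1, ring[k, 2] - rPx):min(ncol(near), ring[k, 2] + rPx)
    near[rows, cols] <- TRUE
  }
  near <- near & g$bioporeLabels == 0L
  ratio <- mean(g$socField[core]) / mean(g$socField[near])
  expect_lt(abs(ratio - 4) / 4, 0.1)
})

test_that("invalid biopore layouts are rejected with clear messages", {
  over <- data.frame(topDepth = c(50, 55), bottomDepth = c(60, 65),
                     center = c(3, 3.1), width = c(6, 6),
                     enrichment = c(2, 2))
  cfg <- syntheticCoreConfig(seed = 1, biopores = over)
  expect_error(generateSOCField(cfg), "overlap")
  expect_error(syntheticCoreConfig(biopores = data.frame(
    topDepth = 50, bottomDepth = 60, center = 0.1, width = 10,
    enrichment = 2)), "outside the core")
  expect_error(syntheticCoreConfig(biopores = data.frame(
    topDepth = 50, bottomDepth = 60, center = 3, width = 6,
    enrichment = 0.5)), "enrichment")
})

test_that("forward model darkens monotonically with SOC at every band", {
  cfg <- quietCoreConfig()
  r <- trueReflectance(matrix(c(2, 16), 1, 2), cfg)
  expect_true(all(r[1, 2, ] < r[1, 1, ]))
})

test_that("noise-free rendering round-trips through target normalization", {
  cfg <- quietCoreConfig(seed = 3, biopores = noBiopores())
  fld <- generateSOCField(cfg)$socField
  rc <- renderCube(fld, cfg)
  norm <- normalizeToTarget(rc$cube, rc$target)
  expect_equal(cubeValues(norm), trueReflectance(fld, cfg),
               tolerance = 1e-12)
})

test_that("equal-SOC pixels with different gains agree after SNV", {
  cfg <- quietCoreConfig()
  s <- trueReflectance(matrix(8, 1, 1), cfg)[1, 1, ]
  out <- snvRows(rbind(0.8 * s, 1.2 * s))
  expect_equal(out[1, ], out[2, ], tolerance = 1e-10)
})

test_that("planted cracks are darker at 980 nm than any soil pixel", {
  tc <- simulateCore(syntheticCoreConfig(seed = 6, crackFraction = 0.02))
  vals <- cubeValues(rawCube(tc))
  b980 <- nearestBand(rawCube(tc), 980)
  crack <- nonSoilMaskTruth(tc)
  expect_gt(sum(crack), 0)
  expect_lt(max(vals[, , b980][crack]), min(vals[, , b980][!crack]))
})

test_that("background columns fall outside the soil 980/420 ratio range", {
  tc <- simulateCore(syntheticCoreConfig(seed = 6, crackFraction = 0,
                                         backgroundCols = 2L))
  vals <- cubeValues(rawCube(tc))
  ratio <- vals[, , nearestBand(rawCube(tc), 980)] /
    vals[, , nearestBand(rawCube(tc), 420)]
  bg <- nonSoilMaskTruth(tc)
  expect_lt(max(ratio[bg]), min(ratio[!bg]))
})

test_that("crackFraction 0 leaves the truth mask empty; >=50% is refused", {
  tc <- simulateCore(syntheticCoreConfig(seed = 2, crackFraction = 0))
  expect_false(any(nonSoilMaskTruth(tc)))
  cfg <- syntheticCoreConfig(seed = 2, crackFraction = 0.4,
                             backgroundCols = 5L)
  fld <- generateSOCField(cfg)
  rc <- renderCube(fld$socField, cfg)
  expect_error(plantNonSoilFeatures(rc$cube, cfg), "50%")
})

test_that("the study cutting scheme yields 33 bulk samples", {
  n <- 0L
  for (i in 1:5) {
    scheme <- if (i <= 3) bulkScheme7() else bulkScheme6()
    bulk <- cutBulkSamples(generateSOCField(
      syntheticCoreConfig(seed = i))$socField, scheme, 2500, seed = i)
    n <- n + nrow(bulk)
  }
  expect_identical(n, 33L)
})

test_that("bulk cutting is exact without noise and validates the scheme", {
  fld <- matrix(5, 400, 24)
  bulk <- cutBulkSamples(fld, bulkScheme7(), 2500, measurementSD = 0)
  expect_equal(bulk$soc, rep(5, 7), tolerance = 1e-12)
  gap <- data.frame(top = c(0, 40), bottom = c(30, 100))
  expect_error(cutBulkSamples(fld, gap, 2500), "gaps or overlaps")
  deep <- data.frame(top = c(0, 30), bottom = c(30, 120))
  expect_error(cutBulkSamples(fld, deep, 2500), "outside the core")
})

test_that("bulk noise is consistent with the configured measurement sd", {
  resids <- unlist(lapply(1:12, function(s) {
    fld <- generateSOCField(syntheticCoreConfig(seed = s))$socField
    b <- cutBulkSamples(fld, bulkScheme7(), 2500, measurementSD = 0.45,
                        seed = s)
    b$soc - b$truthMean
  }))
  # 84 draws from N(0, 0.45): the empirical sd should land near 0.45
  expect_lt(abs(sd(resids) - 0.45) / 0.45, 0.35)
  expect_lt(abs(mean(resids)), 0.2)
})
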