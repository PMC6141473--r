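test_that("metrics match the brute-force oracle on random vectors", {
  set.seed(61)
  for (i in 1:200) {
    n <- sample(2:40, 1)
    m <- rnorm(n, 8, 3)
    p <- m + rnorm(n, 0.5, 1)
    got <- computeMetrics(m, p)
    want <- bruteMetrics(m, p)
    expect_equal(got$me, want$me, tolerance = 1e-12)
    expect_equal(got$rmse, want$rmse, tolerance = 1e-12)
    expect_equal(got$mae, want$mae, tolerance = 1e-12)
    if (sd(m) > 0) {
      expect_equal(got$rpd, want$rpd, tolerance = 1e-12)
      expect_equal(got$r2, want$r2, tolerance = 1e-12)
      # internal identity with the population-sd convention
      expect_equal(got$r2, 1 - 1 / got$rpd^2, tolerance = 1e-12)
    }
  }
})

test_that("perfect and degenerate predictions behave as printed", {
  m <- c(3, 5, 9)
  got <- computeMetrics(m, m)
  expect_equal(got$me, 0)
  expect_equal(got$rmse, 0)
  expect_equal(got$mae, 0)
  expect_identical(got$rpd, Inf)
  expect_equal(got$r2, 1)
  expect_error(computeMetrics(1:3, 1:4), "equal length")
  expect_warning(computeMetrics(c(5, 5, 5), c(4, 5, 6)), "zero variance")
})

test_that("distribution summaries count implausible fractions correctly", {
  mp <- SOCMap(matrix(5, 4, 3), pixelSize = 2500,
               modelInfo = list(socMax = 15.5))
  s <- summarizeDistribution(mp)
  expect_equal(s$mean, 5)
  expect_equal(s$median, 5)
  expect_equal(s$maximum, 5)
  expect_equal(s$minimum, 5)
  expect_equal(s$sd, 0)
  expect_equal(s$proportionBelowZero, 0)
  expect_equal(s$proportionAboveUpper, 0)
  mp2 <- SOCMap(matrix(c(-1, 0.5, 20), 1, 3), pixelSize = 2500,
                modelInfo = list())
  s2 <- summarizeDistribution(mp2, upperLimit = 15.5)
  expect_equal(s2$proportionBelowZero, 1 / 3)
  expect_equal(s2$proportionAboveUpper, 1 / 3)
  # oracle equivalence and ordering invariance
  set.seed(9)
  v <- rnorm(200, 6, 5)
  for (perm in list(seq_along(v), sample(length(v)))) {
    mpp <- SOCMap(matrix(v[perm], 20, 10), pixelSize = 2500,
                  modelInfo = list())
    sp <- summarizeDistribution(mpp, upperLimit = 12)
    want <- bruteSummary(v, 12)
    expect_equal(sp$mean, want$mean, tolerance = 1e-12)
    expect_equal(sp$median, want$median, tolerance = 1e-12)
    expect_equal(sp$sd, want$sd, tolerance = 1e-12)
    expect_equal(sp$proportionBelowZero, want$below, tolerance = 1e-12)
    expect_equal(sp$proportionAboveUpper, want$above, tolerance = 1e-12)
  }
  expect_error(summarizeDistribution(
    SOCMap(matrix(NA_real_, 2, 2), mask = matrix(FALSE, 2, 2),
           pixelSize = 1, modelInfo = list()), upperLimit = 10),
    "no unmasked")
})

test_that("the one-sd envelope projects measured values onto the interval", {
  # slab of constant 6 with planted sd via two pixel values
  mkMap <- function(vals) SOCMap(vals, pixelSize = 1e5, modelInfo = list())
  # rows 0-10 cm (one slab); mean 6, sd 2
  v <- matrix(c(4, 8), 1, 2)
  bulk <- data.frame(depthTop = 0, depthBottom = 10, soc = 5)
  ev <- evaluateBulk(mkMap(v), bulk, statistic = "mean", band = 1)
  expect_equal(ev$slabs$predicted, 6)
  expect_lt(abs(ev$slabs$predictedSD - sd(c(4, 8))), 1e-12)
  expect_equal(ev$slabs$effective, 5)  # inside the envelope -> zero error
  # narrow envelope: projection lands at mean - sd
  v2 <- matrix(c(5.6, 6.4), 1, 2)
  ev2 <- evaluateBulk(mkMap(v2), bulk, statistic = "mean", band = 1)
  expect_equal(ev2$slabs$effective, 6 - sd(c(5.6, 6.4)), tolerance = 1e-12)
  # band = 0 reduces exactly to computeMetrics on the slab statistics
  v3 <- rbind(c(4, 8), c(2, 2))  # two 5 cm slabs: means 6 and 2
  bulk3 <- data.frame(depthTop = c(0, 5), depthBottom = c(5, 10),
                      soc = c(5, 3))
  ev3 <- evaluateBulk(SOCMap(v3, pixelSize = 5e4, modelInfo = list()),
                      bulk3, statistic = "mean", band = 0)
  expect_equal(ev3$metrics, computeMetrics(c(5, 3), c(6, 2)),
               tolerance = 1e-12)
})

test_that("envelope errors never exceed point errors (property)", {
  set.seed(77)
  for (i in 1:20) {
    vals <- matrix(rnorm(40 * 6, 6, 2), 40, 6)
    map <- SOCMap(vals, pixelSize = 2.5e4, modelInfo = list())  # 100 cm
    bulk <- data.frame(depthTop = c(0, 30, 60), depthBottom = c(30, 60, 100),
                       soc = runif(3, 2, 10))
    e0 <- evaluateBulk(map, bulk, band = 0)$slabs
    e1 <- evaluateBulk(map, bulk, band = 1)$slabs
    expect_true(all(abs(e1$effective - e1$measured) <=
                      abs(e0$effective - e0$measured) + 1e-12))
  }
})

test_that("slabs without unmasked pixels are excluded and reported", {
  vals <- matrix(5, 10, 2)
  mask <- matrix(TRUE, 10, 2)
  mask[6:10, ] <- FALSE
  map <- SOCMap(vals, mask = mask, pixelSize = 1e5, modelInfo = list())
  bulk <- data.frame(depthTop = c(0, 50), depthBottom = c(50, 100),
                     soc = c(5, 3))
  ev <- evaluateBulk(map, bulk, band = 0)
  expect_identical(nrow(ev$slabs), 1L)
  expect_identical(nrow(ev$excluded), 1L)
  expect_error(evaluateBulk(map, data.frame(depthTop = 0,
    depthBottom = 150, soc = 5)), "beyond the map")
})

test_that("all four bulk variants are reported for a synthetic core", {
  pc <- preparedCore(seed = 6)
  map <- SOCMap(socField(pc$truth), mask = !nonSoilMaskTruth(pc$truth),
                pixelSize = 2500, modelInfo = list())
  tab <- bulkEvaluationVariants(map, bulkTruth(pc$truth))
  expect_identical(nrow(tab), 4L)
  expect_setequal(tab$variant, c("mean", "median", "mean +/- 1 sd",
                                 "median +/- 1 sd"))
  # envelope variants can only improve RMSE
  expect_lte(tab$rmse[3], tab$rmse[1] + 1e-12)
  expect_lte(tab$rmse[4], tab$rmse[2] + 1e-12)
})

test_that("residual diagnostics recover a planted SOC slope", {
  set.seed(19)
  soc <- runif(120, 2, 14)
  res <- data.frame(resid = -0.2 * (soc - mean(soc)) + rnorm(120, sd = 0.1),
                    soc = soc, horizon = rep(c("topsoil", "subsoil"), 60),
                    column = runif(120, 1, 24))
  d <- residualDepthDiagnostics(res)
  expect_lt(abs(d$socSlope["estimate"] - (-0.2)), 3 * d$socSlope["se"])
  expect_lt(abs(d$columnCorrelation), 3.5 / sqrt(120))
  zero <- data.frame(resid = rep(0, 10), soc = runif(10, 2, 8),
                     horizon = "subsoil", column = 1:10)
  dz <- residualDepthDiagnostics(zero)
  expect_equal(unname(dz$socSlope["estimate"]), 0, tolerance = 1e-12)
  expect_equal(unname(dz$horizonMeans["subsoil"]), 0)
  expect_error(residualDepthDiagnostics(zero[1:3, ]), "at least 5")
})
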