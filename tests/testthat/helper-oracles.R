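# Brute-force oracles, written as plain loops so they stay independent of
# the package's vectorised implementations.

bruteMetrics <- function(measured, predicted) {
  n <- length(measured)
  se <- ae <- e <- 0
  for (i in seq_len(n)) {
    d <- predicted[i] - measured[i]
    e <- e + d
    se <- se + d * d
    ae <- ae + abs(d)
  }
  me <- e / n
  rmse <- sqrt(se / n)
  mae <- ae / n
  mbar <- 0
  for (i in seq_len(n)) mbar <- mbar + measured[i] / n
  ss <- 0
  for (i in seq_len(n)) ss <- ss + (measured[i] - mbar)^2
  sdm <- sqrt(ss / n)
  list(me = me, rmse = rmse, mae = mae,
       rpd = if (rmse == 0) Inf else sdm / rmse,
       r2 = if (rmse == 0) 1 else 1 - se / ss)
}

bruteSummary <- function(values, upper) {
  v <- sort(values)
  n <- length(v)
  med <- if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
  m <- 0
  for (x in v) m <- m + x / n
  ss <- 0
  for (x in v) ss <- ss + (x - m)^2
  below <- above <- 0
  for (x in v) {
    if (x < 0) below <- below + 1
    if (x > upper) above <- above + 1
  }
  list(mean = m, median = med, maximum = v[n], minimum = v[1],
       sd = sqrt(ss / (n - 1)), below = below / n, above = above / n)
}

bruteWindowStats <- function(values, mask, depths, top, bottom) {
  acc <- c()
  for (i in seq_len(nrow(values))) for (j in seq_len(ncol(values))) {
    if (mask[i, j] && depths[i] >= top && depths[i] < bottom &&
        !is.na(values[i, j]))
      acc <- c(acc, values[i, j])
  }
  m <- mean(acc)
  list(mean = m, sd = sd(acc), cv = sd(acc) / m, n = length(acc))
}

bruteROIMean <- function(cube, pixels) {
  vals <- cubeValues(cube)
  nb <- dim(vals)[3L]
  out <- numeric(nb)
  for (b in seq_len(nb)) {
    s <- 0
    for (k in seq_len(nrow(pixels)))
      s <- s + vals[pixels[k, 1L], pixels[k, 2L], b]
    out[b] <- s / nrow(pixels)
  }
  out
}

# explicit rank-1 PLS deflation step (one latent variable), as in the
# textbook NIPALS derivation, kept deliberately naive
bruteOneComponentPLS <- function(X, y, Xnew) {
  xm <- colMeans(X)
  ym <- mean(y)
  E <- sweep(X, 2L, xm)
  f <- y - ym
  w <- as.numeric(t(E) %*% f)
  w <- w / sqrt(sum(w^2))
  t1 <- as.numeric(E %*% w)
  q1 <- sum(f * t1) / sum(t1^2)
  as.numeric(sweep(Xnew, 2L, xm) %*% w) * q1 + ym
}

# small helpers shared across tests --------------------------------------

quietCoreConfig <- function(seed = 1L, ...) {
  syntheticCoreConfig(seed = seed, scatterGainSD = 0, scatterOffsetSD = 0,
                      illuminationGradientAmplitude = 0, bandNoiseSD = 0,
                      crackFraction = 0, ...)
}

noBiopores <- function() {
  data.frame(topDepth = numeric(), bottomDepth = numeric(),
             center = numeric(), width = numeric(), enrichment = numeric())
}

tinyCube <- function(values, wl = NULL, treatment = "normalized_reflectance",
                     pixelSize = 2500) {
  if (is.null(wl)) wl <- seq_len(dim(values)[3L])
  SpectralCube(values, wl, pixelSize, treatment = treatment)
}

# one preprocessed synthetic core: raw -> normalized -> masked -> snv
preparedCore <- function(seed = 1L, ...) {
  tc <- simulateCore(syntheticCoreConfig(seed = seed, ...))
  nr <- maskNonSoil(normalizeToTarget(rawCube(tc), reflectanceTarget(tc)))
  list(truth = tc, nr = nr, snv = snvTransform(nr))
}

validationRMSE <- function(model, cal) {
  info <- calInfo(cal)
  keep <- info$role == "validate"
  p <- predictSpectra(model, calSpectra(cal)[keep, , drop = FALSE])
  sqrt(mean((p - info$soc[keep])^2))
}

singlePointSVMGrid <- function() data.frame(gamma = 0.01, cost = 8,
                                            epsilon = 0.1)
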