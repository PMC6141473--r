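#' Pixel grid implied by a core geometry
#'
#' @param config a \linkS4class{SyntheticCoreConfig}.
#' @return integer vector \code{c(rows, cols)}.
#' @export
pixelGrid <- function(config) {
  stopifnot(is(config, "SyntheticCoreConfig"))
  c(rows = max(2L, round(config@coreHeight * 1e4 / config@pixelSize)),
    cols = max(2L, round(config@coreWidth * 1e4 / config@pixelSize)))
}

#' Noise-free depth profiles of the generator
#'
#' Mean SOC is constant at \code{ploughMeanSOC} above the plough boundary
#' and declines linearly to \code{subsoilSOCAtBottom} at the core bottom;
#' the coefficient of variation interpolates likewise from \code{ploughCV}
#' to \code{subsoilCVAtBottom}.
#'
#' @param config a \linkS4class{SyntheticCoreConfig}.
#' @param depths depths (cm) at which to evaluate; defaults to row centres.
#' @return data.frame with columns depth, mean, cv.
#' @export
truthDepthProfile <- function(config, depths = NULL) {
  if (is.null(depths)) {
    g <- pixelGrid(config)
    depths <- (seq_len(g[["rows"]]) - 0.5) * config@coreHeight / g[["rows"]]
  }
  below <- pmax(0, depths - config@ploughDepth) /
    (config@coreHeight - config@ploughDepth)
  m <- ifelse(depths < config@ploughDepth, config@ploughMeanSOC,
              config@ploughMeanSOC +
                below * (config@subsoilSOCAtBottom - config@ploughMeanSOC))
  cv <- ifelse(depths < config@ploughDepth, config@ploughCV,
               config@ploughCV +
                 below * (config@subsoilCVAtBottom - config@ploughCV))
  data.frame(depth = depths, mean = m, cv = cv)
}

bioporeFootprintWeights <- function(config, rows, cols) {
  # per-biopore weight matrices: 1 inside the channel, linear taper over one
  # pixel at the edge (biopore boundaries in real cores are blurred)
  pxCm <- config@pixelSize / 1e4
  depths <- (seq_len(rows) - 0.5) * pxCm
  xs <- (seq_len(cols) - 0.5) * pxCm
  bp <- config@biopores
  lapply(seq_len(nrow(bp)), function(i) {
    halfW <- bp$width[i] / 20  # mm -> half width in cm
    inRows <- depths >= bp$topDepth[i] & depths < bp$bottomDepth[i]
    dx <- abs(xs - bp$center[i])
    wx <- pmin(1, pmax(0, (halfW + pxCm - dx) / pxCm))
    outer(as.numeric(inRows), wx)
  })
}

#' Generate a ground-truth SOC field
#'
#' Builds a spatially correlated random SOC field following the generator's
#' depth profiles (see \code{\link{truthDepthProfile}}), then plants
#' vertically elongated biopore hotspots whose SOC equals the configured
#' enrichment factor times the local matrix mean.
#'
#' @param config a \linkS4class{SyntheticCoreConfig}.
#' @return list with \code{socField} (matrix, mg/g), \code{horizonBoundary}
#'   (cm), \code{bioporeTruth} (data.frame) and \code{bioporeLabels}
#'   (integer matrix; 0 = matrix soil).
#' @export
generateSOCField <- function(config) {
  stopifnot(is(config, "SyntheticCoreConfig"))
  validObject(config)
  g <- pixelGrid(config)
  rows <- g[["rows"]]; cols <- g[["cols"]]
  prof <- truthDepthProfile(config)
  bp <- config@biopores
  if (nrow(bp) >= 2L) {
    # reject overlapping footprints: the truth labels would be ambiguous
    halfW <- bp$width / 20
    pxCm <- config@pixelSize / 1e4
    for (i in seq_len(nrow(bp) - 1L)) for (j in (i + 1L):nrow(bp)) {
      sepX <- abs(bp$center[i] - bp$center[j]) >
        (halfW[i] + halfW[j] + 2 * pxCm)
      sepD <- bp$topDepth[i] >= bp$bottomDepth[j] ||
        bp$topDepth[j] >= bp$bottomDepth[i]
      if (!sepX && !sepD)
        stop("biopores ", i, " and ", j, " overlap; adjust their placement")
    }
  }
  field <- withSeed(substreamSeed(config@seed, "soc_field"), {
    z <- matrix(stats::rnorm(rows * cols), rows, cols)
    sigma <- 2000 / config@pixelSize  # ~2 mm correlation length
    z <- gaussianSmooth(z, sigma)
    if (stats::sd(as.vector(z)) > 0)
      z <- (z - mean(z)) / stats::sd(as.vector(z))
    matrix(prof$mean, rows, cols) * (1 + matrix(prof$cv, rows, cols) * z)
  })
  labels <- matrix(0L, rows, cols)
  if (nrow(bp) > 0L) {
    wts <- bioporeFootprintWeights(config, rows, cols)
    for (i in seq_along(wts)) {
      w <- wts[[i]]
      bpSOC <- matrix(prof$mean, rows, cols) * bp$enrichment[i]
      field <- (1 - w) * field + w * bpSOC
      labels[w >= 0.999] <- i
    }
  }
  field <- pmax(field, 0.05)  # strictly positive truth
  truth <- cbind(label = seq_len(nrow(bp)), bp)
  list(socField = field, horizonBoundary = config@ploughDepth,
       bioporeTruth = truth, bioporeLabels = labels)
}

forwardOptics <- function(config) {
  wl <- seq(config@wavelengthMin, config@wavelengthMax,
            length.out = config@nBands)
  u <- (wl - config@wavelengthMin) / (config@wavelengthMax - config@wavelengthMin)
  list(wavelengths = wl,
       baseline = 0.12 + 0.38 * u,          # soils brighten toward the NIR
       k = 0.065 - 0.045 * u,               # SOC darkens VIS more than NIR
       lamp = 0.6 + 1.8 * u - 0.8 * u^2)    # smooth positive lamp spectrum
}

#' True reflectance implied by the forward model
#'
#' \eqn{r(\lambda) = baseline(\lambda) \exp(-k(\lambda) \cdot SOC)}: a
#' smooth, monotone-in-SOC, nonlinear darkening with stronger sensitivity
#' in the visible than the NIR, so that linear and nonlinear regressors
#' genuinely differ on the rendered spectra.
#'
#' @param socField matrix of SOC (mg/g).
#' @param config a \linkS4class{SyntheticCoreConfig}.
#' @return 3D array of reflectance (rows x cols x bands).
#' @export
trueReflectance <- function(socField, config) {
  opt <- forwardOptics(config)
  r <- array(0, c(dim(socField), config@nBands))
  for (b in seq_len(config@nBands))
    r[, , b] <- opt$baseline[b] * exp(-opt$k[b] * socField)
  r
}

#' Render the raw hyperspectral cube of a synthetic core
#'
#' Recorded intensity per pixel and band is
#' \code{g(x) a(px) r(lambda) L(lambda) + b(px) + noise}, where \code{g} is
#' a horizontal illumination gradient, \code{a}/\code{b} are per-pixel
#' multiplicative/additive scatter, \code{L} the lamp spectrum and \code{r}
#' the true reflectance (\code{\link{trueReflectance}}). The reflectance
#' target is rendered as \code{g(x) R_defined L(lambda)} without scatter.
#'
#' @param socField matrix of true SOC (mg/g), strictly positive.
#' @param config a \linkS4class{SyntheticCoreConfig}.
#' @param definedReflectance reflectance of the calibration target (~0.5).
#' @return list with \code{cube} (raw \linkS4class{SpectralCube}) and
#'   \code{target} (\linkS4class{ReflectanceTarget}).
#' @export
renderCube <- function(socField, config, definedReflectance = 0.5) {
  stopifnot(all(socField > 0))
  rows <- nrow(socField); cols <- ncol(socField)
  opt <- forwardOptics(config)
  r <- trueReflectance(socField, config)
  gx <- if (cols > 1L)
    1 + config@illuminationGradientAmplitude *
      (2 * (seq_len(cols) - 1) / (cols - 1) - 1)
  else 1
  vals <- withSeed(substreamSeed(config@seed, "render"), {
    a <- exp(matrix(stats::rnorm(rows * cols, sd = config@scatterGainSD),
                    rows, cols))
    bOff <- matrix(stats::rnorm(rows * cols, sd = config@scatterOffsetSD),
                   rows, cols)
    out <- array(0, dim(r))
    for (b in seq_len(config@nBands)) {
      noise <- if (config@bandNoiseSD > 0)
        matrix(stats::rnorm(rows * cols, sd = config@bandNoiseSD), rows, cols)
      else 0
      out[, , b] <- sweep(a * r[, , b], 2L, gx, `*`) * opt$lamp[b] +
        bOff + noise
    }
    out
  })
  vals <- pmax(vals, 0)
  cube <- SpectralCube(vals, opt$wavelengths, config@pixelSize)
  targetI <- outer(if (length(gx) == 1L) rep(gx, cols) else gx,
                   definedReflectance * opt$lamp)
  target <- ReflectanceTarget(targetI, definedReflectance)
  list(cube = cube, target = target)
}

#' Plant non-soil features into a rendered cube
#'
#' Cracks and macropores are rendered dark across all bands (in particular
#' at ~980 nm, below the soil-pixel intensity range); holder/background
#' columns are rendered spectrally flat, giving a 980/420 band ratio
#' outside the soil range. The truth mask records every altered pixel.
#'
#' @param cube a raw \linkS4class{SpectralCube}.
#' @param config a \linkS4class{SyntheticCoreConfig}.
#' @return list with \code{cube} (modified) and \code{nonSoilMaskTruth}
#'   (logical matrix).
#' @export
plantNonSoilFeatures <- function(cube, config) {
  vals <- cubeValues(cube)
  rows <- dim(vals)[1L]; cols <- dim(vals)[2L]
  truth <- matrix(FALSE, rows, cols)
  frac <- config@crackFraction +
    config@backgroundCols / max(1L, cols)
  if (frac >= 0.5)
    stop("non-soil features would cover >= 50% of the core; refusing")
  nCrack <- round(config@crackFraction * rows * cols)
  if (nCrack > 0L) {
    crack <- withSeed(substreamSeed(config@seed, "cracks"), {
      sel <- matrix(FALSE, rows, cols)
      while (sum(sel) < nCrack) {
        r0 <- sample.int(rows, 1L)
        c0 <- sample.int(cols, 1L)
        len <- sample(4:15, 1L)
        cc <- c0
        for (dr in 0:(len - 1L)) {
          r <- r0 + dr
          if (r > rows) break
          cc <- min(cols, max(1L, cc + sample(c(-1L, 0L, 0L, 1L), 1L)))
          sel[r, cc] <- TRUE
        }
      }
      sel
    })
    for (b in seq_len(dim(vals)[3L]))
      vals[, , b][crack] <- 0.03 * vals[, , b][crack]
    truth <- truth | crack
  }
  if (config@backgroundCols > 0L) {
    opt <- forwardOptics(config)
    gx <- if (cols > 1L)
      1 + config@illuminationGradientAmplitude *
        (2 * (seq_len(cols) - 1) / (cols - 1) - 1)
    else 1
    bgCols <- (cols - config@backgroundCols + 1L):cols
    for (b in seq_len(dim(vals)[3L]))
      vals[, bgCols, b] <- matrix(0.30 * opt$lamp[b] * gx[bgCols],
                                  rows, length(bgCols), byrow = TRUE)
    truth[, bgCols] <- TRUE
  }
  list(cube = SpectralCube(vals, wavelengths(cube), pixelSize(cube),
                           mask = soilMask(cube),
                           depthOrigin = depthOrigin(cube)),
       nonSoilMaskTruth = truth)
}

#' Standard bulk-sample cutting schemes
#'
#' Depth intervals used when half-cores are cut for laboratory analysis:
#' the 7-increment scheme 0-30, 30-45, 45-50, 50-60, 60-70, 70-78,
#' 78-100 cm, and the 6-increment variant that merges 30-45 and 45-50 cm
#' into 30-50 cm.
#'
#' @return data.frame with columns \code{top} and \code{bottom} (cm).
#' @export
bulkScheme7 <- function() data.frame(
  top = c(0, 30, 45, 50, 60, 70, 78),
  bottom = c(30, 45, 50, 60, 70, 78, 100))

#' @rdname bulkScheme7
#' @export
bulkScheme6 <- function() data.frame(
  top = c(0, 30, 50, 60, 70, 78),
  bottom = c(30, 50, 60, 70, 78, 100))

#' Cut bulk samples from a truth field
#'
#' Each bulk value is the mean of the truth field over its depth slab plus
#' analytical measurement noise.
#'
#' @param socField matrix of true SOC (mg/g).
#' @param scheme data.frame with columns \code{top}, \code{bottom} (cm);
#'   intervals must be contiguous, non-overlapping and within the core.
#' @param pixelSize pixel size (micrometres).
#' @param measurementSD sd of Gaussian measurement noise (mg/g).
#' @param seed integer seed.
#' @param depthOrigin depth (cm) of the field's first row.
#' @return data.frame with columns depthTop, depthBottom, truthMean, soc.
#' @export
cutBulkSamples <- function(socField, scheme, pixelSize,
                           measurementSD = 0.45, seed = 1L,
                           depthOrigin = 0) {
  stopifnot(all(c("top", "bottom") %in% names(scheme)))
  o <- order(scheme$top)
  scheme <- scheme[o, , drop = FALSE]
  if (any(scheme$bottom <= scheme$top))
    stop("each interval must have bottom > top")
  if (nrow(scheme) > 1L &&
      any(abs(scheme$top[-1L] - scheme$bottom[-nrow(scheme)]) > 1e-9))
    stop("cutting scheme has gaps or overlaps between intervals")
  depths <- depthOrigin + (seq_len(nrow(socField)) - 0.5) * pixelSize / 1e4
  if (min(scheme$top) < depthOrigin - 1e-9 ||
      max(scheme$bottom) > depthOrigin + nrow(socField) * pixelSize / 1e4 + 1e-9)
    stop("cutting scheme extends outside the core")
  truthMean <- vapply(seq_len(nrow(scheme)), function(i) {
    rows <- depths >= scheme$top[i] & depths < scheme$bottom[i]
    mean(socField[rows, , drop = FALSE])
  }, numeric(1))
  noise <- withSeed(seed, stats::rnorm(nrow(scheme), sd = measurementSD))
  data.frame(depthTop = scheme$top, depthBottom = scheme$bottom,
             truthMean = truthMean, soc = truthMean + noise)
}

#' Simulate one complete synthetic soil core
#'
#' Runs field generation, cube rendering and non-soil feature planting, and
#' cuts the bulk-sample truth with the given scheme.
#'
#' @param config a \linkS4class{SyntheticCoreConfig}.
#' @param scheme bulk cutting scheme (data.frame top/bottom, cm); default
#'   the 7-increment scheme.
#' @return a \linkS4class{GroundTruthCore}.
#' @export
simulateCore <- function(config = syntheticCoreConfig(),
                         scheme = bulkScheme7()) {
  fld <- generateSOCField(config)
  rend <- renderCube(fld$socField, config)
  feat <- plantNonSoilFeatures(rend$cube, config)
  bulk <- cutBulkSamples(fld$socField, scheme, config@pixelSize,
                         measurementSD = config@socMeasurementSD,
                         seed = substreamSeed(config@seed, "bulk"))
  new("GroundTruthCore", socField = fld$socField, cube = feat$cube,
      target = rend$target, nonSoilMaskTruth = feat$nonSoilMaskTruth,
      horizonBoundary = fld$horizonBoundary,
      bioporeTruth = fld$bioporeTruth, bioporeLabels = fld$bioporeLabels,
      bulkTruth = bulk, config = config)
}
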