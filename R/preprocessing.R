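#' Index of the band nearest a wavelength
#' @param object a SpectralCube (or numeric wavelength vector).
#' @param nm target wavelength in nm.
#' @return integer band index.
#' @export
nearestBand <- function(object, nm) {
  wl <- if (is(object, "SpectralCube")) wavelengths(object) else object
  which.min(abs(wl - nm))
}

#' Normalize a raw cube to the reflectance target
#'
#' Converts recorded intensity to reflectance per wavelength and pixel
#' column:
#' \deqn{R_{sample,\lambda,x} = \frac{I_{sample,\lambda,x}}{I_{target,\lambda,x}} \cdot R_{target,\lambda,defined}}
#' Because the target is divided out column by column, horizontal
#' illumination differences cancel.
#'
#' @param raw a raw-tagged \linkS4class{SpectralCube}.
#' @param target a \linkS4class{ReflectanceTarget} covering every band and
#'   column of the cube.
#' @return a \linkS4class{SpectralCube} tagged
#'   \code{"normalized_reflectance"}.
#' @export
normalizeToTarget <- function(raw, target) {
  stopifnot(is(raw, "SpectralCube"), is(target, "ReflectanceTarget"))
  if (treatment(raw) != "raw")
    stop("normalizeToTarget expects a raw-intensity cube, got treatment '",
         treatment(raw), "'")
  vals <- cubeValues(raw)
  d <- dim(vals)
  ti <- target@intensity
  if (nrow(ti) != d[2L] || ncol(ti) != d[3L])
    stop("target scan shape (", nrow(ti), " cols x ", ncol(ti),
         " bands) does not cover the cube (", d[2L], " x ", d[3L], ")")
  bad <- which(!is.finite(ti) | ti <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-positive target intensity at column ", bad[1L, 1L],
         ", band ", bad[1L, 2L])
  out <- vals
  for (b in seq_len(d[3L]))
    out[, , b] <- sweep(vals[, , b], 2L,
                        ti[, b] / target@definedReflectance[b], `/`)
  SpectralCube(out, wavelengths(raw), pixelSize(raw), mask = soilMask(raw),
               depthOrigin = depthOrigin(raw),
               treatment = "normalized_reflectance",
               metadata = raw@metadata)
}

#' Mask non-soil pixels by NIR level and 980/420 band ratio
#'
#' Pixels whose reflectance at the band nearest 980 nm falls below
#' \code{upperBandThreshold} (translation-stage background, shadows,
#' cracks, macropores) or whose 980/420 band ratio falls outside
#' \code{ratioBounds} (sample holder, spectrally flat background) are
#' marked unusable. Spectral values are never altered, only the mask.
#' Raising \code{upperBandThreshold} can only mask additional pixels.
#'
#' @param cube a normalized \linkS4class{SpectralCube}.
#' @param upperBandThreshold minimum acceptable reflectance at ~980 nm;
#'   default 0.15, calibrated so clean synthetic soil is never masked.
#' @param ratioBounds length-2 numeric: acceptable (980 nm)/(420 nm) ratio
#'   range for soil; default \code{c(1.5, 12)}.
#' @param upperNM,lowerNM wavelengths (nm) of the two masking bands.
#' @return the cube with an updated mask; the number of newly masked
#'   pixels is recorded in \code{metadata$maskedNonSoil}.
#' @export
maskNonSoil <- function(cube, upperBandThreshold = 0.15,
                        ratioBounds = c(1.5, 12),
                        upperNM = 980, lowerNM = 420) {
  stopifnot(is(cube, "SpectralCube"))
  if (treatment(cube) != "normalized_reflectance")
    stop("maskNonSoil expects a normalized_reflectance cube")
  vals <- cubeValues(cube)
  bU <- nearestBand(cube, upperNM)
  bL <- nearestBand(cube, lowerNM)
  upper <- vals[, , bU]
  lower <- vals[, , bL]
  ratio <- ifelse(lower > 0, upper / lower, Inf)
  bad <- upper < upperBandThreshold |
    ratio < ratioBounds[1L] | ratio > ratioBounds[2L]
  newMask <- soilMask(cube) & !bad
  if (!any(newMask))
    warning("masking thresholds removed 100% of pixels")
  md <- cube@metadata
  md$maskedNonSoil <- sum(soilMask(cube) & bad)
  SpectralCube(vals, wavelengths(cube), pixelSize(cube), mask = newMask,
               depthOrigin = depthOrigin(cube), treatment = treatment(cube),
               metadata = md)
}

#' Standard normal variate (SNV) transform
#'
#' Z-scores each pixel spectrum over its bands: \eqn{s \to (s - \bar s)/sd(s)}
#' with the sample (n-1) standard deviation. SNV removes per-pixel
#' multiplicative and additive scatter: \code{snv(a*s + b) == snv(s)} for
#' any \code{a > 0}. Pixels with a flat (zero-sd) spectrum cannot be
#' transformed; they are masked and counted in
#' \code{metadata$flatPixelCount}.
#'
#' @param cube a \code{normalized_reflectance} \linkS4class{SpectralCube}.
#' @return an \code{"snv"}-tagged cube.
#' @export
snvTransform <- function(cube) {
  stopifnot(is(cube, "SpectralCube"))
  if (treatment(cube) != "normalized_reflectance")
    stop("snvTransform expects a normalized_reflectance cube")
  vals <- cubeValues(cube)
  d <- dim(vals)
  mat <- matrix(vals, d[1L] * d[2L], d[3L])
  mu <- rowMeans(mat)
  sdv <- sqrt(rowSums((mat - mu)^2) / (d[3L] - 1L))
  flat <- sdv == 0 | !is.finite(sdv)
  sdv[flat] <- 1
  out <- array((mat - mu) / sdv, d)
  mask <- soilMask(cube) & !matrix(flat, d[1L], d[2L])
  md <- cube@metadata
  md$flatPixelCount <- sum(flat & soilMask(cube))
  SpectralCube(out, wavelengths(cube), pixelSize(cube), mask = mask,
               depthOrigin = depthOrigin(cube), treatment = "snv",
               metadata = md)
}

#' SNV transform of a spectra matrix
#' @param spectra numeric matrix, one spectrum per row.
#' @return matrix of the same shape (rows with zero sd become NA).
#' @export
snvRows <- function(spectra) {
  mu <- rowMeans(spectra)
  sdv <- apply(spectra, 1L, stats::sd)
  out <- (spectra - mu) / sdv
  out[sdv == 0, ] <- NA_real_
  out
}

#' Per-band scaling of spectra to the unit interval
#'
#' Affine map of each band to [0, 1] using the calibration-set minimum and
#' maximum (required by the SVM, which needs standardized predictors). The
#' stored parameters are applied unchanged to prediction spectra, whose
#' values may then fall outside [0, 1]. Constant bands are mapped to 0.5
#' and flagged.
#'
#' @param spectra numeric matrix (samples x bands) with finite values.
#' @return list with \code{scaled} matrix, \code{min}, \code{max} per band
#'   and \code{constantBands} (integer indices).
#' @export
scaleToUnitInterval <- function(spectra) {
  stopifnot(is.matrix(spectra), all(is.finite(spectra)))
  mn <- apply(spectra, 2L, min)
  mx <- apply(spectra, 2L, max)
  constant <- which(mx == mn)
  rng <- mx - mn
  rng[constant] <- 1
  scaled <- sweep(sweep(spectra, 2L, mn, `-`), 2L, rng, `/`)
  scaled[, constant] <- 0.5
  list(scaled = scaled, min = mn, max = mx,
       constantBands = constant)
}

#' @rdname scaleToUnitInterval
#' @param scaling a scaling object from \code{scaleToUnitInterval}.
#' @export
applyUnitScaling <- function(spectra, scaling) {
  rng <- scaling$max - scaling$min
  rng[scaling$constantBands] <- 1
  out <- sweep(sweep(spectra, 2L, scaling$min, `-`), 2L, rng, `/`)
  if (length(scaling$constantBands))
    out[, scaling$constantBands] <- 0.5
  out
}

#' @rdname scaleToUnitInterval
#' @export
unscaleFromUnitInterval <- function(spectra, scaling) {
  rng <- scaling$max - scaling$min
  rng[scaling$constantBands] <- 1
  out <- sweep(sweep(spectra, 2L, rng, `*`), 2L, scaling$min, `+`)
  if (length(scaling$constantBands))
    out[, scaling$constantBands] <- scaling$min[scaling$constantBands]
  out
}

#' Principal-component false-colour rendering of a cube
#'
#' Fits a PCA (mean-centred, unscaled) on the unmasked pixel spectra of one
#' core and returns the first \code{nComponents} score images, each
#' min-max stretched to [0, 1], as an RGB-style false-colour array. The
#' sign of each loading vector is fixed by making its largest-magnitude
#' element positive, so renderings are reproducible.
#'
#' @param cube a normalized or SNV \linkS4class{SpectralCube}.
#' @param nComponents number of components (default 3).
#' @return list with \code{image} (rows x cols x nComponents array, NA at
#'   masked pixels), \code{loadings} (bands x nComponents),
#'   \code{explainedVariance} (fraction per component) and \code{scores}
#'   (matrix over unmasked pixels).
#' @export
pcaRGB <- function(cube, nComponents = 3L) {
  stopifnot(is(cube, "SpectralCube"))
  if (!treatment(cube) %in% c("normalized_reflectance", "snv"))
    stop("pcaRGB expects a normalized_reflectance or snv cube")
  vals <- cubeValues(cube)
  d <- dim(vals)
  if (d[3L] < nComponents) stop("fewer bands than components")
  mask <- soilMask(cube)
  if (sum(mask) < nComponents)
    stop("fewer unmasked pixels (", sum(mask), ") than components")
  mat <- matrix(vals, d[1L] * d[2L], d[3L])[as.vector(mask), , drop = FALSE]
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  nk <- min(nComponents, ncol(pc$rotation))
  load <- pc$rotation[, seq_len(nk), drop = FALSE]
  flip <- vapply(seq_len(nk), function(k) {
    j <- which.max(abs(load[, k]))
    if (load[j, k] < 0) -1 else 1
  }, numeric(1))
  load <- sweep(load, 2L, flip, `*`)
  scores <- sweep(pc$x[, seq_len(nk), drop = FALSE], 2L, flip, `*`)
  img <- array(NA_real_, c(d[1L], d[2L], nk))
  for (k in seq_len(nk)) {
    plane <- matrix(NA_real_, d[1L], d[2L])
    sk <- scores[, k]
    rngk <- range(sk)
    stretch <- if (diff(rngk) > 0) (sk - rngk[1L]) / diff(rngk) else
      rep(0.5, length(sk))
    plane[mask] <- stretch
    img[, , k] <- plane
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(image = img, loadings = load,
       explainedVariance = ev[seq_len(nk)], scores = scores)
}
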