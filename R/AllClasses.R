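#' @import methods
NULL

setClassUnion("ListOrNULL", c("list", "NULL"))
setClassUnion("DataFrameOrNULL", c("data.frame", "NULL"))

#' SpectralCube: a hyperspectral soil-core image
#'
#' A 3D raster (rows = depth pixels, columns = horizontal pixels, third
#' dimension = spectral bands) with its wavelength axis, pixel size, a soil
#' mask and a depth origin. The \code{treatment} tag records which spectral
#' processing stage the values represent: \code{"raw"} instrument intensity,
#' \code{"normalized_reflectance"} after reflectance-target normalization,
#' \code{"snv"} after the standard normal variate transform, or
#' \code{"unit_scaled"}.
#'
#' @slot values numeric 3D array (rows x cols x bands).
#' @slot wavelengths numeric vector of band-centre wavelengths (nm),
#'   strictly increasing, one per band.
#' @slot pixelSize pixel edge length in micrometres.
#' @slot mask logical matrix (rows x cols); \code{TRUE} = usable soil pixel.
#' @slot depthOrigin depth (cm) of the top edge of row 1.
#' @slot treatment character tag, see above.
#' @slot metadata free-form list (e.g. flat-pixel counters).
#' @export
setClass("SpectralCube",
  representation(values = "array", wavelengths = "numeric",
                 pixelSize = "numeric", mask = "matrix",
                 depthOrigin = "numeric", treatment = "character",
                 metadata = "list"),
  prototype(depthOrigin = 0, treatment = "raw", metadata = list()))

setValidity("SpectralCube", function(object) {
  v <- object@values
  msg <- character()
  if (length(dim(v)) != 3L) msg <- c(msg, "values must be a 3D array")
  else {
    if (dim(v)[3L] != length(object@wavelengths))
      msg <- c(msg, "band count must equal wavelength count")
    if (!all(dim(object@mask) == dim(v)[1:2]))
      msg <- c(msg, "mask shape must equal spatial shape")
  }
  if (length(object@wavelengths) >= 2L &&
      any(diff(object@wavelengths) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (!object@treatment %in%
      c("raw", "normalized_reflectance", "snv", "unit_scaled"))
    msg <- c(msg, "unknown treatment tag")
  if (length(msg)) msg else TRUE
})

#' Construct a SpectralCube
#'
#' @param values 3D numeric array (rows x cols x bands).
#' @param wavelengths band wavelengths (nm), strictly increasing.
#' @param pixelSize pixel size in micrometres.
#' @param mask logical matrix; defaults to all-\code{TRUE}.
#' @param depthOrigin depth (cm) of the top of the image.
#' @param treatment treatment tag.
#' @param metadata list of auxiliary entries.
#' @return a \linkS4class{SpectralCube}.
#' @export
SpectralCube <- function(values, wavelengths, pixelSize,
                         mask = NULL, depthOrigin = 0,
                         treatment = "raw", metadata = list()) {
  if (is.null(mask)) mask <- matrix(TRUE, dim(values)[1L], dim(values)[2L])
  new("SpectralCube", values = values, wavelengths = as.numeric(wavelengths),
      pixelSize = as.numeric(pixelSize), mask = mask,
      depthOrigin = as.numeric(depthOrigin), treatment = treatment,
      metadata = metadata)
}

#' ReflectanceTarget: reference scan of the calibration target
#'
#' Per-column, per-band intensity of a panel of known reflectance, scanned
#' before the samples. Normalizing sample intensity by the target intensity
#' column-wise cancels horizontal illumination differences.
#'
#' @slot intensity numeric matrix (columns x bands), strictly positive.
#' @slot definedReflectance numeric vector per band in (0, 1].
#' @export
setClass("ReflectanceTarget",
  representation(intensity = "matrix", definedReflectance = "numeric"))

setValidity("ReflectanceTarget", function(object) {
  msg <- character()
  if (ncol(object@intensity) != length(object@definedReflectance))
    msg <- c(msg, "definedReflectance must have one value per band")
  if (any(!is.finite(object@intensity)) || any(object@intensity <= 0))
    msg <- c(msg, "target intensity must be strictly positive and finite")
  if (any(object@definedReflectance <= 0 | object@definedReflectance > 1))
    msg <- c(msg, "definedReflectance must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname ReflectanceTarget-class
#' @param intensity columns x bands intensity matrix.
#' @param definedReflectance per-band defined reflectance.
#' @export
ReflectanceTarget <- function(intensity, definedReflectance) {
  if (length(definedReflectance) == 1L)
    definedReflectance <- rep(definedReflectance, ncol(intensity))
  new("ReflectanceTarget", intensity = intensity,
      definedReflectance = as.numeric(definedReflectance))
}

#' SyntheticCoreConfig: parameters of the synthetic soil-core generator
#'
#' Defaults emulate a cultivated loess soil profile: a well-mixed plough
#' horizon (0--30 cm) of ~9 mg g\eqn{^{-1}} SOC with coefficient of
#' variation ~0.2, below which mean SOC declines approximately linearly to
#' ~2 mg g\eqn{^{-1}} at 1 m while the coefficient of variation rises to
#' ~0.7, plus vertically elongated biopore hotspots enriched 2--10 fold
#' over the adjacent matrix.
#'
#' @slot coreHeight,coreWidth core dimensions (cm).
#' @slot pixelSize pixel size (micrometres).
#' @slot nBands number of spectral bands.
#' @slot wavelengthMin,wavelengthMax spectral range (nm).
#' @slot ploughDepth plough-horizon depth (cm).
#' @slot ploughMeanSOC mean SOC in the plough horizon (mg/g).
#' @slot ploughCV coefficient of variation in the plough horizon.
#' @slot subsoilSOCAtBottom mean SOC at the core bottom (mg/g).
#' @slot subsoilCVAtBottom coefficient of variation at the core bottom.
#' @slot biopores data.frame with columns topDepth, bottomDepth (cm),
#'   center (cm from the left edge), width (mm), enrichment (fold).
#' @slot crackFraction fraction of core pixels turned into cracks/macropores.
#' @slot backgroundCols number of image columns rendered as holder/background.
#' @slot scatterGainSD,scatterOffsetSD per-pixel multiplicative (log scale)
#'   and additive scatter standard deviations.
#' @slot illuminationGradientAmplitude relative amplitude of the horizontal
#'   illumination gradient.
#' @slot bandNoiseSD per-band additive intensity noise sd.
#' @slot socMeasurementSD sd (mg/g) of the analytical noise on ROI and bulk
#'   SOC values; default 0.45, half the 0.9 mg/g limit of determination of
#'   dry-combustion carbon analysis.
#' @slot seed integer seed.
#' @export
setClass("SyntheticCoreConfig",
  representation(coreHeight = "numeric", coreWidth = "numeric",
    pixelSize = "numeric", nBands = "integer",
    wavelengthMin = "numeric", wavelengthMax = "numeric",
    ploughDepth = "numeric", ploughMeanSOC = "numeric", ploughCV = "numeric",
    subsoilSOCAtBottom = "numeric", subsoilCVAtBottom = "numeric",
    biopores = "data.frame", crackFraction = "numeric",
    backgroundCols = "integer",
    scatterGainSD = "numeric", scatterOffsetSD = "numeric",
    illuminationGradientAmplitude = "numeric", bandNoiseSD = "numeric",
    socMeasurementSD = "numeric", seed = "integer"))

setValidity("SyntheticCoreConfig", function(object) {
  msg <- character()
  pos <- c(coreHeight = object@coreHeight, coreWidth = object@coreWidth,
           pixelSize = object@pixelSize)
  if (any(pos <= 0)) msg <- c(msg, "all lengths must be > 0")
  if (object@ploughDepth >= object@coreHeight)
    msg <- c(msg, "ploughDepth must be < coreHeight")
  if (object@wavelengthMax <= object@wavelengthMin)
    msg <- c(msg, "wavelengthMax must exceed wavelengthMin")
  if (object@nBands < 2L) msg <- c(msg, "nBands must be >= 2")
  if (object@ploughCV < 0 || object@ploughCV >= 1 ||
      object@subsoilCVAtBottom < 0 || object@subsoilCVAtBottom >= 1)
    msg <- c(msg, "coefficients of variation must lie in [0, 1)")
  bp <- object@biopores
  if (nrow(bp) > 0) {
    need <- c("topDepth", "bottomDepth", "center", "width", "enrichment")
    if (!all(need %in% names(bp)))
      msg <- c(msg, paste("biopores needs columns:", paste(need, collapse = ", ")))
    else {
      if (any(bp$enrichment < 1)) msg <- c(msg, "enrichment must be >= 1")
      if (any(bp$topDepth < 0 | bp$bottomDepth > object@coreHeight |
              bp$topDepth >= bp$bottomDepth))
        msg <- c(msg, "biopore depth extents must lie inside the core")
      halfW <- bp$width / 20  # mm -> cm, half width
      if (any(bp$center - halfW < 0 | bp$center + halfW > object@coreWidth))
        msg <- c(msg, "biopore footprint extends outside the core width")
    }
  }
  if (object@crackFraction < 0 || object@crackFraction >= 0.5)
    msg <- c(msg, "crackFraction must lie in [0, 0.5)")
  if (length(msg)) msg else TRUE
})

#' @rdname SyntheticCoreConfig-class
#'
#' @param coreHeight,coreWidth,pixelSize,nBands,wavelengthMin,wavelengthMax
#'   geometry and spectral axis; defaults: 100 x 6 cm core, 2500 um pixels
#'   (a 400 x 24 grid that keeps simulations fast; set 53 for the full
#'   instrument resolution), 186 bands over 400--990 nm.
#' @param ploughDepth,ploughMeanSOC,ploughCV plough-horizon depth (30 cm),
#'   mean SOC (9 mg/g) and coefficient of variation (0.2).
#' @param subsoilSOCAtBottom,subsoilCVAtBottom mean SOC (2 mg/g) and CV
#'   (0.7) at the core bottom; both interpolate linearly with depth below
#'   the plough boundary.
#' @param biopores data.frame of planted biopores (see slots); the default
#'   plants three subsoil biopores with enrichments 2.5, 3 and 4.
#' @param crackFraction fraction of pixels rendered as cracks/macropores.
#' @param backgroundCols trailing image columns rendered as sample holder.
#' @param scatterGainSD,scatterOffsetSD,illuminationGradientAmplitude,bandNoiseSD
#'   optical nuisance terms of the forward model.
#' @param socMeasurementSD analytical noise sd on SOC measurements (mg/g).
#' @param seed integer seed; fixed seed implies a bit-identical core.
#' @export
syntheticCoreConfig <- function(coreHeight = 100, coreWidth = 6,
    pixelSize = 2500, nBands = 186L,
    wavelengthMin = 400, wavelengthMax = 990,
    ploughDepth = 30, ploughMeanSOC = 9, ploughCV = 0.2,
    subsoilSOCAtBottom = 2, subsoilCVAtBottom = 0.7,
    biopores = defaultBiopores(), crackFraction = 0.01,
    backgroundCols = 0L,
    scatterGainSD = 0.1, scatterOffsetSD = 0.005,
    illuminationGradientAmplitude = 0.1, bandNoiseSD = 0.003,
    socMeasurementSD = 0.45, seed = 1L) {
  new("SyntheticCoreConfig", coreHeight = coreHeight, coreWidth = coreWidth,
      pixelSize = pixelSize, nBands = as.integer(nBands),
      wavelengthMin = wavelengthMin, wavelengthMax = wavelengthMax,
      ploughDepth = ploughDepth, ploughMeanSOC = ploughMeanSOC,
      ploughCV = ploughCV, subsoilSOCAtBottom = subsoilSOCAtBottom,
      subsoilCVAtBottom = subsoilCVAtBottom, biopores = biopores,
      crackFraction = crackFraction,
      backgroundCols = as.integer(backgroundCols),
      scatterGainSD = scatterGainSD, scatterOffsetSD = scatterOffsetSD,
      illuminationGradientAmplitude = illuminationGradientAmplitude,
      bandNoiseSD = bandNoiseSD, socMeasurementSD = socMeasurementSD,
      seed = as.integer(seed))
}

#' Default planted biopores
#'
#' Three vertically elongated subsoil biopores patterned on channels
#' observed in cultivated loess subsoils: depth extents ~35--45, ~53--64
#' and ~69--83 cm with enrichment factors 2.5, 3 and 4 over the adjacent
#' matrix.
#' @return data.frame with one row per biopore.
#' @export
defaultBiopores <- function() {
  data.frame(
    topDepth = c(35, 53, 69),
    bottomDepth = c(45, 64, 83),
    center = c(1.5, 4.5, 3.0),
    width = c(6, 6, 7),
    enrichment = c(2.5, 3, 4))
}

#' GroundTruthCore: a synthetic core with its rendered image and truth
#'
#' @slot socField matrix of true SOC (mg/g) per pixel.
#' @slot cube raw-intensity \linkS4class{SpectralCube}.
#' @slot target \linkS4class{ReflectanceTarget} scan.
#' @slot nonSoilMaskTruth logical matrix; \code{TRUE} where a non-soil
#'   feature (crack, macropore, holder) was rendered.
#' @slot horizonBoundary plough/subsoil boundary depth (cm).
#' @slot bioporeTruth data.frame of planted biopores (footprint label id,
#'   enrichment, depth extent).
#' @slot bioporeLabels integer matrix labelling planted biopore pixels.
#' @slot bulkTruth data.frame of bulk-sample truth (or NULL before cutting).
#' @slot config the generating \linkS4class{SyntheticCoreConfig}.
#' @export
setClass("GroundTruthCore",
  representation(socField = "matrix", cube = "SpectralCube",
    target = "ReflectanceTarget", nonSoilMaskTruth = "matrix",
    horizonBoundary = "numeric", bioporeTruth = "data.frame",
    bioporeLabels = "matrix", bulkTruth = "DataFrameOrNULL",
    config = "SyntheticCoreConfig"))

setValidity("GroundTruthCore", function(object) {
  msg <- character()
  if (any(object@socField <= 0)) msg <- c(msg, "socField must be strictly positive")
  if (any(object@cube@values < 0)) msg <- c(msg, "raw cube must be non-negative")
  if (!all(dim(object@socField) == dim(object@cube@values)[1:2]))
    msg <- c(msg, "socField and cube spatial shapes differ")
  if (!all(dim(object@nonSoilMaskTruth) == dim(object@socField)))
    msg <- c(msg, "nonSoilMaskTruth shape differs from socField")
  if (length(msg)) msg else TRUE
})

#' CalibrationSet: ROI-level spectra paired with measured SOC
#'
#' One row of \code{info} per calibration sample: the ROI it came from, the
#' summarising statistic (mean or median), the subset id (\code{full} or
#' \code{r1..r5} random 1\% subsets), the role (train/validate), the
#' measured SOC and the ROI location (centroid depth, centroid column,
#' horizon label). \code{spectra} holds the matching spectra row-wise.
#'
#' @slot spectra numeric matrix (samples x bands).
#' @slot info data.frame describing each row of \code{spectra}.
#' @slot treatment spectral treatment tag of the spectra.
#' @slot socMin,socMax calibration limits: range of measured ROI SOC (mg/g).
#' @slot wavelengths band wavelengths (nm).
#' @export
setClass("CalibrationSet",
  representation(spectra = "matrix", info = "data.frame",
                 treatment = "character", socMin = "numeric",
                 socMax = "numeric", wavelengths = "numeric"))

setValidity("CalibrationSet", function(object) {
  msg <- character()
  if (nrow(object@spectra) != nrow(object@info))
    msg <- c(msg, "spectra and info must have matching rows")
  need <- c("roiId", "statistic", "subsetId", "role", "soc")
  if (!all(need %in% names(object@info)))
    msg <- c(msg, paste("info needs columns:", paste(need, collapse = ", ")))
  if (length(object@socMin) == 1L && length(object@socMax) == 1L &&
      object@socMin >= object@socMax)
    msg <- c(msg, "socMin must be < socMax (degenerate calibration)")
  if (length(msg)) msg else TRUE
})

#' BiasCorrection: depth-stratified additive offsets
#'
#' Residual bias of tree-ensemble SOC predictions depends on vertical
#' position (regression to the mean under-estimates carbon-rich topsoil and
#' over-estimates carbon-poor subsoil); the correction adds a constant
#' offset per horizon, split at \code{horizonBoundary}.
#'
#' @slot topsoilOffset,subsoilOffset additive offsets (mg/g).
#' @slot horizonBoundary boundary depth (cm).
#' @slot diagnostics list (e.g. residual-vs-column correlation).
#' @export
setClass("BiasCorrection",
  representation(topsoilOffset = "numeric", subsoilOffset = "numeric",
                 horizonBoundary = "numeric", diagnostics = "list"),
  prototype(diagnostics = list()))

setValidity("BiasCorrection", function(object) {
  if (!is.finite(object@topsoilOffset) || !is.finite(object@subsoilOffset))
    return("offsets must be finite")
  TRUE
})

#' @rdname BiasCorrection-class
#' @param topsoilOffset,subsoilOffset additive offsets (mg/g).
#' @param horizonBoundary boundary depth (cm).
#' @param diagnostics optional diagnostics list.
#' @export
BiasCorrection <- function(topsoilOffset, subsoilOffset, horizonBoundary,
                           diagnostics = list()) {
  new("BiasCorrection", topsoilOffset = topsoilOffset,
      subsoilOffset = subsoilOffset, horizonBoundary = horizonBoundary,
      diagnostics = diagnostics)
}

#' FittedSOCModel: a calibrated spectra-to-SOC regressor
#'
#' @slot algorithm one of \code{"pls"}, \code{"rf"}, \code{"svm"}.
#' @slot fit the fitted model object (algorithm-specific).
#' @slot hyperparameters list of chosen hyperparameters (e.g. number of PLS
#'   components; gamma/cost/epsilon and support-vector count for SVM).
#' @slot treatment spectral treatment the model expects.
#' @slot socMin,socMax calibration limits (mg/g).
#' @slot scaling unit-interval scaling parameters (SVM) or NULL.
#' @slot biasCorrection optional \linkS4class{BiasCorrection}.
#' @slot wavelengths band wavelengths the model was trained on.
#' @slot seed integer seed used in fitting.
#' @export
setClass("FittedSOCModel",
  representation(algorithm = "character", fit = "ANY",
    hyperparameters = "list", treatment = "character",
    socMin = "numeric", socMax = "numeric", scaling = "ListOrNULL",
    biasCorrection = "ANY", wavelengths = "numeric", seed = "integer"),
  prototype(scaling = NULL, biasCorrection = NULL))

setValidity("FittedSOCModel", function(object) {
  msg <- character()
  if (!object@algorithm %in% c("pls", "rf", "svm"))
    msg <- c(msg, "algorithm must be pls, rf or svm")
  if (!is.finite(object@socMin) || !is.finite(object@socMax))
    msg <- c(msg, "calibration limits must be finite")
  if (length(msg)) msg else TRUE
})

#' SOCMap: per-pixel SOC predictions for one core
#'
#' \code{values} carries the current map (possibly constrained and/or
#' bias-corrected); \code{rawValues} always preserves the unadjusted model
#' output. Masked pixels are \code{NA} in both.
#'
#' @slot values numeric matrix of SOC (mg/g), NA where masked.
#' @slot rawValues numeric matrix of unadjusted predictions.
#' @slot mask logical matrix (TRUE = usable soil pixel).
#' @slot pixelSize micrometres.
#' @slot depthOrigin cm of the top edge of row 1.
#' @slot adjustments character vector of applied steps (e.g.
#'   \code{"constrained"}, \code{"bias_corrected"}).
#' @slot modelInfo list describing the generating model.
#' @export
setClass("SOCMap",
  representation(values = "matrix", rawValues = "matrix", mask = "matrix",
    pixelSize = "numeric", depthOrigin = "numeric",
    adjustments = "character", modelInfo = "list"),
  prototype(adjustments = character(), modelInfo = list(), depthOrigin = 0))

setValidity("SOCMap", function(object) {
  msg <- character()
  if (!all(dim(object@values) == dim(object@mask)) ||
      !all(dim(object@rawValues) == dim(object@mask)))
    msg <- c(msg, "values, rawValues and mask shapes must agree")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname SOCMap-class
#' @param values matrix of SOC predictions (NA where masked).
#' @param mask logical matrix.
#' @param pixelSize micrometres.
#' @param depthOrigin cm.
#' @param rawValues optional unadjusted predictions (defaults to values).
#' @param adjustments character vector of applied adjustments.
#' @param modelInfo list.
#' @export
SOCMap <- function(values, mask = NULL, pixelSize, depthOrigin = 0,
                   rawValues = values, adjustments = character(),
                   modelInfo = list()) {
  if (is.null(mask)) mask <- !is.na(values)
  new("SOCMap", values = values, rawValues = rawValues, mask = mask,
      pixelSize = pixelSize, depthOrigin = depthOrigin,
      adjustments = adjustments, modelInfo = modelInfo)
}
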