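#' Accessors for socmap classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object a socmap S4 object.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cubeValues", function(object) standardGeneric("cubeValues"))
#' @rdname accessors
#' @export
setMethod("cubeValues", "SpectralCube", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(object) standardGeneric("wavelengths"))
#' @rdname accessors
#' @export
setMethod("wavelengths", "SpectralCube", function(object) object@wavelengths)
#' @rdname accessors
#' @export
setMethod("wavelengths", "CalibrationSet", function(object) object@wavelengths)
#' @rdname accessors
#' @export
setMethod("wavelengths", "FittedSOCModel", function(object) object@wavelengths)

#' @rdname accessors
#' @export
setGeneric("soilMask", function(object) standardGeneric("soilMask"))
#' @rdname accessors
#' @export
setMethod("soilMask", "SpectralCube", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("soilMask", "SOCMap", function(object) object@mask)

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setMethod("pixelSize", "SpectralCube", function(object) object@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "SOCMap", function(object) object@pixelSize)

#' @rdname accessors
#' @export
setGeneric("depthOrigin", function(object) standardGeneric("depthOrigin"))
#' @rdname accessors
#' @export
setMethod("depthOrigin", "SpectralCube", function(object) object@depthOrigin)
#' @rdname accessors
#' @export
setMethod("depthOrigin", "SOCMap", function(object) object@depthOrigin)

#' @rdname accessors
#' @export
setGeneric("treatment", function(object) standardGeneric("treatment"))
#' @rdname accessors
#' @export
setMethod("treatment", "SpectralCube", function(object) object@treatment)
#' @rdname accessors
#' @export
setMethod("treatment", "CalibrationSet", function(object) object@treatment)
#' @rdname accessors
#' @export
setMethod("treatment", "FittedSOCModel", function(object) object@treatment)

#' @rdname accessors
#' @export
setGeneric("socValues", function(object) standardGeneric("socValues"))
#' @rdname accessors
#' @export
setMethod("socValues", "SOCMap", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("rawValues", function(object) standardGeneric("rawValues"))
#' @rdname accessors
#' @export
setMethod("rawValues", "SOCMap", function(object) object@rawValues)

#' @rdname accessors
#' @export
setGeneric("adjustments", function(object) standardGeneric("adjustments"))
#' @rdname accessors
#' @export
setMethod("adjustments", "SOCMap", function(object) object@adjustments)

#' @rdname accessors
#' @export
setGeneric("socField", function(object) standardGeneric("socField"))
#' @rdname accessors
#' @export
setMethod("socField", "GroundTruthCore", function(object) object@socField)

#' @rdname accessors
#' @export
setGeneric("rawCube", function(object) standardGeneric("rawCube"))
#' @rdname accessors
#' @export
setMethod("rawCube", "GroundTruthCore", function(object) object@cube)

#' @rdname accessors
#' @export
setGeneric("reflectanceTarget", function(object) standardGeneric("reflectanceTarget"))
#' @rdname accessors
#' @export
setMethod("reflectanceTarget", "GroundTruthCore", function(object) object@target)

#' @rdname accessors
#' @export
setGeneric("nonSoilMaskTruth", function(object) standardGeneric("nonSoilMaskTruth"))
#' @rdname accessors
#' @export
setMethod("nonSoilMaskTruth", "GroundTruthCore", function(object) object@nonSoilMaskTruth)

#' @rdname accessors
#' @export
setGeneric("horizonBoundary", function(object) standardGeneric("horizonBoundary"))
#' @rdname accessors
#' @export
setMethod("horizonBoundary", "GroundTruthCore", function(object) object@horizonBoundary)
#' @rdname accessors
#' @export
setMethod("horizonBoundary", "BiasCorrection", function(object) object@horizonBoundary)

#' @rdname accessors
#' @export
setGeneric("bioporeTruth", function(object) standardGeneric("bioporeTruth"))
#' @rdname accessors
#' @export
setMethod("bioporeTruth", "GroundTruthCore", function(object) object@bioporeTruth)

#' @rdname accessors
#' @export
setGeneric("bioporeLabels", function(object) standardGeneric("bioporeLabels"))
#' @rdname accessors
#' @export
setMethod("bioporeLabels", "GroundTruthCore", function(object) object@bioporeLabels)

#' @rdname accessors
#' @export
setGeneric("bulkTruth", function(object) standardGeneric("bulkTruth"))
#' @rdname accessors
#' @export
setMethod("bulkTruth", "GroundTruthCore", function(object) object@bulkTruth)

#' @rdname accessors
#' @export
setGeneric("calSpectra", function(object) standardGeneric("calSpectra"))
#' @rdname accessors
#' @export
setMethod("calSpectra", "CalibrationSet", function(object) object@spectra)

#' @rdname accessors
#' @export
setGeneric("calInfo", function(object) standardGeneric("calInfo"))
#' @rdname accessors
#' @export
setMethod("calInfo", "CalibrationSet", function(object) object@info)

#' @rdname accessors
#' @export
setGeneric("calibrationLimits", function(object) standardGeneric("calibrationLimits"))
#' @rdname accessors
#' @export
setMethod("calibrationLimits", "CalibrationSet", function(object)
  c(socMin = object@socMin, socMax = object@socMax))
#' @rdname accessors
#' @export
setMethod("calibrationLimits", "FittedSOCModel", function(object)
  c(socMin = object@socMin, socMax = object@socMax))

#' @rdname accessors
#' @export
setGeneric("algorithm", function(object) standardGeneric("algorithm"))
#' @rdname accessors
#' @export
setMethod("algorithm", "FittedSOCModel", function(object) object@algorithm)

#' @rdname accessors
#' @export
setGeneric("hyperparameters", function(object) standardGeneric("hyperparameters"))
#' @rdname accessors
#' @export
setMethod("hyperparameters", "FittedSOCModel", function(object) object@hyperparameters)

#' @rdname accessors
#' @export
setGeneric("biasCorrection", function(object) standardGeneric("biasCorrection"))
#' @rdname accessors
#' @export
setMethod("biasCorrection", "FittedSOCModel", function(object) object@biasCorrection)

#' @rdname accessors
#' @export
setGeneric("biasOffsets", function(object) standardGeneric("biasOffsets"))
#' @rdname accessors
#' @export
setMethod("biasOffsets", "BiasCorrection", function(object)
  c(topsoil = object@topsoilOffset, subsoil = object@subsoilOffset))

#' Depth (cm) of each pixel row centre
#'
#' Row 1 starts at the depth origin; depth increases with the row index.
#' Intervals throughout the package are half-open \code{[top, bottom)}.
#'
#' @param object a SpectralCube or SOCMap.
#' @return numeric vector of row-centre depths in cm.
#' @export
setGeneric("rowDepths", function(object) standardGeneric("rowDepths"))
#' @rdname rowDepths
#' @export
setMethod("rowDepths", "SOCMap", function(object)
  object@depthOrigin + (seq_len(nrow(object@values)) - 0.5) *
    object@pixelSize / 1e4)
#' @rdname rowDepths
#' @export
setMethod("rowDepths", "SpectralCube", function(object)
  object@depthOrigin + (seq_len(dim(object@values)[1L]) - 0.5) *
    object@pixelSize / 1e4)

setMethod("show", "SpectralCube", function(object) {
  d <- dim(object@values)
  cat(sprintf("SpectralCube: %d x %d pixels, %d bands (%.0f-%.0f nm)\n",
              d[1L], d[2L], d[3L], min(object@wavelengths),
              max(object@wavelengths)))
  cat(sprintf("  pixel size %.0f um | treatment: %s | usable pixels: %d/%d\n",
              object@pixelSize, object@treatment, sum(object@mask),
              length(object@mask)))
})

setMethod("show", "GroundTruthCore", function(object) {
  cat(sprintf("GroundTruthCore: %d x %d px, SOC %.2f-%.2f mg/g, %d biopore(s)\n",
              nrow(object@socField), ncol(object@socField),
              min(object@socField), max(object@socField),
              nrow(object@bioporeTruth)))
  cat(sprintf("  plough boundary at %.0f cm | non-soil pixels: %d\n",
              object@horizonBoundary, sum(object@nonSoilMaskTruth)))
})

setMethod("show", "CalibrationSet", function(object) {
  cat(sprintf("CalibrationSet: %d samples (%d train / %d validate), %d bands\n",
              nrow(object@spectra), sum(object@info$role == "train"),
              sum(object@info$role == "validate"), ncol(object@spectra)))
  cat(sprintf("  treatment: %s | SOC limits [%.2f, %.2f] mg/g\n",
              object@treatment, object@socMin, object@socMax))
})

setMethod("show", "FittedSOCModel", function(object) {
  cat(sprintf("FittedSOCModel: %s on %s spectra\n",
              toupper(object@algorithm), object@treatment))
  hp <- object@hyperparameters
  if (length(hp))
    cat("  ", paste(names(hp), vapply(hp, function(x)
      paste(format(x), collapse = ","), ""), sep = "=", collapse = " | "),
      "\n", sep = "")
  cat(sprintf("  calibration limits [%.2f, %.2f] mg/g | bias correction: %s\n",
              object@socMin, object@socMax,
              if (is.null(object@biasCorrection)) "none" else "yes"))
})

setMethod("show", "SOCMap", function(object) {
  v <- object@values[object@mask]
  cat(sprintf("SOCMap: %d x %d px (%d predicted)\n",
              nrow(object@values), ncol(object@values), sum(object@mask)))
  if (length(v))
    cat(sprintf("  SOC mean %.2f, range [%.2f, %.2f] mg/g | adjustments: %s\n",
                mean(v, na.rm = TRUE), min(v, na.rm = TRUE),
                max(v, na.rm = TRUE),
                if (length(object@adjustments))
                  paste(object@adjustments, collapse = ", ") else "none"))
})

setMethod("show", "BiasCorrection", function(object) {
  cat(sprintf("BiasCorrection: topsoil %+0.3f, subsoil %+0.3f mg/g, boundary %.0f cm\n",
              object@topsoilOffset, object@subsoilOffset,
              object@horizonBoundary))
})
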