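#' Equal-area depth profile of a SOC map
#'
#' Tiles the core from the surface down into windows of equal height (full
#' core width) and computes, over the unmasked pixels of each window, the
#' mean, standard deviation, coefficient of variation (sd/mean), skew
#' (adjusted Fisher-Pearson standardized third moment) and pixel count.
#' The last window may be partial and is reported with its true count.
#'
#' @param map a \linkS4class{SOCMap}.
#' @param windowHeightCm window height in cm (default 6, i.e. ~6 x 6 cm
#'   windows on a 6 cm core).
#' @return data.frame with one row per window: depthTop, depthBottom,
#'   depthMid, mean, sd, cv, skew, nPixels. Windows without unmasked pixels
#'   are dropped.
#' @export
depthProfile <- function(map, windowHeightCm = 6) {
  stopifnot(is(map, "SOCMap"), windowHeightCm > 0)
  depths <- rowDepths(map)
  lo <- depthOrigin(map)
  hi <- lo + nrow(socValues(map)) * pixelSize(map) / 1e4
  if (windowHeightCm > hi - lo) {
    warning("window taller than the core; using a single window")
    windowHeightCm <- hi - lo
  }
  tops <- seq(lo, hi - 1e-9, by = windowHeightCm)
  v <- socValues(map)
  v[!soilMask(map)] <- NA
  rows <- lapply(tops, function(tp) {
    bt <- min(tp + windowHeightCm, hi)
    px <- v[depths >= tp & depths < bt, , drop = FALSE]
    px <- px[!is.na(px)]
    if (length(px) == 0L) return(NULL)
    m <- mean(px)
    s <- if (length(px) > 1L) stats::sd(px) else 0
    data.frame(depthTop = tp, depthBottom = bt, depthMid = (tp + bt) / 2,
               mean = m, sd = s, cv = if (m != 0) s / m else NA_real_,
               skew = skewnessAdj(px), nPixels = length(px))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ratio of region SOC to its adjacent matrix SOC
#'
#' @param regionSoc SOC of the enriched/depleted region (mg/g).
#' @param matrixSoc SOC of the directly adjacent soil matrix (mg/g), > 0.
#' @return the unitless enrichment factor (> 1: enriched; < 1: depleted).
#' @export
#' @examples
#' enrichmentFactor(16, 4)  # a biopore four-fold enriched over its matrix
enrichmentFactor <- function(regionSoc, matrixSoc) {
  if (any(matrixSoc <= 0))
    stop("matrix SOC must be positive; enrichment undefined")
  regionSoc / matrixSoc
}

#' Detect SOC hotspots and coldspots
#'
#' Candidate pixels are those whose SOC exceeds \code{enrichmentThreshold}
#' times the local background (the median of a square neighbourhood of
#' radius \code{annulusRadiusCm}); candidates are grouped into 8-connected
#' regions, and regions smaller than \code{minRegionPx} are discarded. Each
#' surviving region is quantified against its own annulus: the median SOC
#' of the ring of pixels within \code{annulusRadiusCm} of the region
#' boundary, excluding the region itself (the median is robust to
#' neighbouring hotspots). Coldspots are detected analogously with SOC
#' below background/threshold.
#'
#' @param map a \linkS4class{SOCMap} (typically the bias-corrected map).
#' @param enrichmentThreshold candidacy threshold (default 2).
#' @param annulusRadiusCm matrix-reference radius in cm (default 1,
#'   matching the "directly adjacent" soil at < 1 cm distance).
#' @param minRegionPx smallest reported region, in pixels (default 2).
#' @param statistic region statistic, \code{"mean"} or \code{"max"}.
#' @param coldspots also detect depleted regions (default TRUE).
#' @return data.frame with one row per region: classification, pixel count,
#'   depth extent (cm), region statistic, matrix reference (annulus
#'   median), enrichment factor and a region label. The label raster is
#'   attached as attribute \code{"labels"} (positive ids = hotspots,
#'   negative = coldspots).
#' @export
detectHotspots <- function(map, enrichmentThreshold = 2,
                           annulusRadiusCm = 1, minRegionPx = 2L,
                           statistic = c("mean", "max"),
                           coldspots = TRUE) {
  statistic <- match.arg(statistic)
  stopifnot(is(map, "SOCMap"), enrichmentThreshold > 1)
  v <- socValues(map)
  v[!soilMask(map)] <- NA
  rPx <- max(1L, round(annulusRadiusCm * 1e4 / pixelSize(map)))
  bg <- ringMedianBackground(v, ro = rPx + 2L, ri = 1L)
  depths <- rowDepths(map)
  labels <- matrix(0L, nrow(v), ncol(v))
  quantify <- function(cand, sign) {
    cand[is.na(cand)] <- FALSE
    lab <- labelConnected(cand)
    out <- list()
    for (id in seq_len(max(lab))) {
      region <- lab == id
      if (sum(region) < minRegionPx) next
      ring <- dilateMask(region, rPx) & !region
      ringVals <- v[ring]
      ringVals <- ringVals[!is.na(ringVals)]
      regVals <- v[region]
      stat <- if (statistic == "mean") mean(regVals) else max(regVals)
      ref <- if (length(ringVals) > 0L) stats::median(ringVals) else
        NA_real_
      ef <- if (!is.na(ref) && ref > 0) enrichmentFactor(stat, ref) else
        NA_real_
      regRows <- which(rowSums(region) > 0)
      newId <- sign * (length(out) + 1L +
                         if (sign > 0) 0L else 0L)
      out[[length(out) + 1L]] <- data.frame(
        classification = if (sign > 0) "hotspot" else "coldspot",
        nPixels = sum(region),
        depthTopCm = depths[min(regRows)] - pixelSize(map) / 2e4,
        depthBottomCm = depths[max(regRows)] + pixelSize(map) / 2e4,
        regionSoc = stat, matrixSoc = ref, enrichment = ef,
        referenceDefined = length(ringVals) > 0L)
      labels[region] <<- newId
    }
    out
  }
  hot <- quantify(!is.na(v) & !is.na(bg) & v > enrichmentThreshold * bg, 1L)
  cold <- if (coldspots)
    quantify(!is.na(v) & !is.na(bg) & bg > 0 &
               v < bg / enrichmentThreshold, -1L)
  else list()
  out <- do.call(rbind, c(hot, cold))
  if (is.null(out))
    out <- data.frame(classification = character(), nPixels = integer(),
                      depthTopCm = numeric(), depthBottomCm = numeric(),
                      regionSoc = numeric(), matrixSoc = numeric(),
                      enrichment = numeric(), referenceDefined = logical())
  rownames(out) <- NULL
  attr(out, "labels") <- labels
  out
}

#' Match detected hotspots to planted biopores
#'
#' For each planted biopore, finds the detected hotspot overlapping its
#' footprint (if any) and pairs the recovered enrichment factor with the
#' planted one.
#'
#' @param detections output of \code{\link{detectHotspots}} run on a map of
#'   the same geometry as the truth.
#' @param truth a \linkS4class{GroundTruthCore}.
#' @return data.frame with one row per planted biopore: planted enrichment,
#'   detected (logical) and recovered enrichment (NA if undetected).
#' @export
matchBioporeDetections <- function(detections, truth) {
  stopifnot(is(truth, "GroundTruthCore"))
  lab <- attr(detections, "labels")
  bt <- bioporeTruth(truth)
  bl <- bioporeLabels(truth)
  hotIds <- which(detections$classification == "hotspot")
  out <- lapply(seq_len(nrow(bt)), function(i) {
    foot <- bl == bt$label[i]
    overl <- lab[foot]
    overl <- overl[overl > 0L]
    if (length(overl) == 0L)
      return(data.frame(label = bt$label[i], planted = bt$enrichment[i],
                        detected = FALSE, recovered = NA_real_))
    best <- as.integer(names(sort(table(overl), decreasing = TRUE))[1L])
    row <- hotIds[best]
    data.frame(label = bt$label[i], planted = bt$enrichment[i],
               detected = TRUE, recovered = detections$enrichment[row])
  })
  do.call(rbind, out)
}
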