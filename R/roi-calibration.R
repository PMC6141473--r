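#' RegionOfInterest: a calibration sampling region
#'
#' A contiguous set of unmasked pixels on one core face that was physically
#' sub-sampled for laboratory carbon analysis; its measured SOC anchors the
#' spectral calibration.
#'
#' @slot roiId character identifier.
#' @slot pixels integer matrix with columns \code{row}, \code{col}.
#' @slot coreId character core identifier.
#' @slot depthCm centroid depth (cm).
#' @slot column centroid horizontal pixel position.
#' @slot horizon \code{"topsoil"} or \code{"subsoil"}.
#' @slot measuredSoc laboratory SOC (mg/g), > 0.
#' @slot areaCm2 region area (cm^2).
#' @export
setClass("RegionOfInterest",
  representation(roiId = "character", pixels = "matrix", coreId = "character",
    depthCm = "numeric", column = "numeric", horizon = "character",
    measuredSoc = "numeric", areaCm2 = "numeric"))

setValidity("RegionOfInterest", function(object) {
  msg <- character()
  if (ncol(object@pixels) != 2L) msg <- c(msg, "pixels must have 2 columns")
  if (object@measuredSoc <= 0) msg <- c(msg, "measuredSoc must be > 0")
  if (!object@horizon %in% c("topsoil", "subsoil"))
    msg <- c(msg, "horizon must be 'topsoil' or 'subsoil'")
  if (length(msg)) msg else TRUE
})

#' @rdname RegionOfInterest-class
#' @param roiId,coreId identifiers.
#' @param pixels two-column integer matrix (row, col).
#' @param measuredSoc laboratory SOC (mg/g).
#' @param pixelSize micrometres (for area and depth).
#' @param depthOrigin cm of row 1.
#' @param horizonBoundaryCm boundary used for the horizon label.
#' @export
regionOfInterest <- function(roiId, pixels, measuredSoc, pixelSize,
                             coreId = "core1", depthOrigin = 0,
                             horizonBoundaryCm = 30) {
  pixels <- as.matrix(pixels)
  colnames(pixels) <- c("row", "col")
  depthCm <- depthOrigin + (mean(pixels[, 1L]) - 0.5) * pixelSize / 1e4
  new("RegionOfInterest", roiId = as.character(roiId), pixels = pixels,
      coreId = as.character(coreId), depthCm = depthCm,
      column = mean(pixels[, 2L]),
      horizon = if (depthCm < horizonBoundaryCm) "topsoil" else "subsoil",
      measuredSoc = measuredSoc,
      areaCm2 = nrow(pixels) * (pixelSize / 1e4)^2)
}

roundHalfUp <- function(x) floor(x + 0.5)

#' Extract the representative spectra of one ROI
#'
#' Returns twelve spectra per region: the bandwise mean and median of (1)
#' all pixels in the ROI and (2) five separate random subsets of 1\% of the
#' ROI pixels (size \code{max(1, roundHalfUp(0.01 n))}, drawn without
#' replacement, each subset drawn independently). Subset membership is
#' deterministic for a fixed seed.
#'
#' @param cube a \linkS4class{SpectralCube} (normalized or SNV).
#' @param roi a \linkS4class{RegionOfInterest} whose pixels are unmasked.
#' @param seed integer seed for the subset draws.
#' @param minPixels smallest acceptable ROI pixel count.
#' @return list with \code{spectra} (12 x bands matrix) and \code{info}
#'   (data.frame with columns statistic, subsetId).
#' @export
extractROISpectra <- function(cube, roi, seed = 1L, minPixels = 4L) {
  stopifnot(is(cube, "SpectralCube"), is(roi, "RegionOfInterest"))
  px <- roi@pixels
  d <- dim(cubeValues(cube))
  if (nrow(px) < minPixels)
    stop("ROI ", roi@roiId, " has ", nrow(px), " pixels; minimum is ",
         minPixels)
  if (any(px[, 1L] < 1L | px[, 1L] > d[1L] | px[, 2L] < 1L | px[, 2L] > d[2L]))
    stop("ROI ", roi@roiId, " has pixels outside the cube")
  mask <- soilMask(cube)
  if (any(!mask[px]))
    stop("ROI ", roi@roiId, " contains masked pixels")
  vals <- cubeValues(cube)
  flat <- matrix(vals, d[1L] * d[2L], d[3L])
  pixIdx <- (px[, 2L] - 1L) * d[1L] + px[, 1L]
  spec <- flat[pixIdx, , drop = FALSE]
  subsetSize <- max(1L, roundHalfUp(0.01 * nrow(spec)))
  subsets <- withSeed(seed, lapply(1:5, function(i)
    sample.int(nrow(spec), subsetSize)))
  groups <- c(list(full = seq_len(nrow(spec))),
              stats::setNames(subsets, paste0("r", 1:5)))
  meanRows <- t(vapply(groups, function(g)
    colMeans(spec[g, , drop = FALSE]), numeric(d[3L])))
  medianRows <- t(vapply(groups, function(g)
    apply(spec[g, , drop = FALSE], 2L, stats::median), numeric(d[3L])))
  list(spectra = rbind(meanRows, medianRows),
       info = data.frame(
         statistic = rep(c("mean", "median"), each = 6L),
         subsetId = rep(names(groups), 2L)))
}

#' Assemble the calibration/validation table
#'
#' For each ROI the chosen statistic's spectra are split into roles the way
#' the calibration design prescribes: three randomly chosen 1\%-subset
#' spectra train the model; the full-ROI spectrum plus the remaining two
#' subsets validate it. The calibration limits \code{socMin}/\code{socMax}
#' are the range of measured ROI SOC.
#'
#' @param rois list of \linkS4class{RegionOfInterest}.
#' @param cubes a \linkS4class{SpectralCube} or named list of cubes keyed
#'   by \code{coreId}.
#' @param statistic \code{"mean"} (default; better suited for prediction)
#'   or \code{"median"}.
#' @param seed integer seed (subset draws and train/validate assignment).
#' @param minPixels forwarded to \code{\link{extractROISpectra}}.
#' @return a \linkS4class{CalibrationSet}.
#' @export
buildCalibrationSet <- function(rois, cubes, statistic = c("mean", "median"),
                                seed = 1L, minPixels = 4L) {
  statistic <- match.arg(statistic)
  if (length(rois) < 2L) stop("need at least 2 ROIs")
  socs <- vapply(rois, function(r) r@measuredSoc, numeric(1))
  if (length(unique(socs)) < 2L)
    stop("all ROIs share one SOC value; calibration is degenerate")
  if (is(cubes, "SpectralCube")) {
    ids <- unique(vapply(rois, function(r) r@coreId, character(1)))
    cubes <- stats::setNames(rep(list(cubes), length(ids)), ids)
  }
  treatments <- unique(vapply(cubes, treatment, character(1)))
  if (length(treatments) != 1L)
    stop("all cubes in a calibration set must share one treatment")
  specList <- list(); infoList <- list()
  for (i in seq_along(rois)) {
    roi <- rois[[i]]
    cube <- cubes[[roi@coreId]]
    if (is.null(cube)) stop("no cube supplied for core ", roi@coreId)
    ex <- extractROISpectra(cube, roi,
                            seed = substreamSeed(seed, paste0("roi_", roi@roiId)),
                            minPixels = minPixels)
    keep <- ex$info$statistic == statistic
    spec <- ex$spectra[keep, , drop = FALSE]
    info <- ex$info[keep, , drop = FALSE]
    trainSubsets <- withSeed(
      substreamSeed(seed, paste0("split_", roi@roiId)),
      sample(paste0("r", 1:5), 3L))
    info$role <- ifelse(info$subsetId %in% trainSubsets, "train", "validate")
    info$roiId <- roi@roiId
    info$coreId <- roi@coreId
    info$soc <- roi@measuredSoc
    info$depthCm <- roi@depthCm
    info$column <- roi@column
    info$horizon <- roi@horizon
    specList[[i]] <- spec
    infoList[[i]] <- info
  }
  info <- do.call(rbind, infoList)
  rownames(info) <- NULL
  new("CalibrationSet", spectra = do.call(rbind, specList), info = info,
      treatment = treatments, socMin = min(socs), socMax = max(socs),
      wavelengths = wavelengths(cubes[[1L]]))
}

#' Automated ROI placement on a synthetic core
#'
#' Emulates manual ROI selection: square regions are placed at random over
#' the unmasked core face, stratified by depth (a quarter in the plough
#' horizon, the rest in the subsoil), with a share of regions deliberately
#' placed at the extremes of the first principal-component score (or of the
#' truth field) to maximise calibration variance. Measured SOC is the truth
#' mean over the region plus analytical noise.
#'
#' @param cube a masked, normalized \linkS4class{SpectralCube}.
#' @param truthField matrix of true SOC (mg/g) matching the cube.
#' @param n number of ROIs requested (default 71).
#' @param roiHalf half-width of the square ROI in pixels (1 = 3x3).
#' @param topsoilFraction fraction of ROIs placed above the boundary.
#' @param horizonBoundaryCm plough/subsoil boundary depth (cm).
#' @param extremeFraction fraction of ROIs anchored at score extremes.
#' @param measurementSD analytical noise sd (mg/g).
#' @param coreId core identifier carried by the ROIs.
#' @param seed integer seed.
#' @return list of \linkS4class{RegionOfInterest}; fewer than \code{n}
#'   (with a warning) if the unmasked area cannot host them.
#' @export
selectROIsAuto <- function(cube, truthField, n = 71L, roiHalf = 1L,
                           topsoilFraction = 0.25, horizonBoundaryCm = 30,
                           extremeFraction = 0.2, measurementSD = 0.45,
                           coreId = "core1", seed = 1L) {
  stopifnot(is(cube, "SpectralCube"), is.matrix(truthField))
  d <- dim(cubeValues(cube))
  stopifnot(all(dim(truthField) == d[1:2]))
  mask <- soilMask(cube)
  if (!any(mask)) stop("cube is fully masked; cannot place ROIs")
  side <- 2L * roiHalf + 1L
  ok <- matrix(FALSE, d[1L], d[2L])
  rows <- (roiHalf + 1L):(d[1L] - roiHalf)
  cols <- (roiHalf + 1L):(d[2L] - roiHalf)
  for (i in rows) for (j in cols)
    ok[i, j] <- all(mask[(i - roiHalf):(i + roiHalf),
                         (j - roiHalf):(j + roiHalf)])
  if (!any(ok)) stop("no unmasked region can host an ROI of side ", side)
  depths <- depthOrigin(cube) + (seq_len(d[1L]) - 0.5) * pixelSize(cube) / 1e4
  topRows <- depths < horizonBoundaryCm
  nTop <- round(topsoilFraction * n)
  nExtreme <- round(extremeFraction * n)
  score <- truthField  # extreme-variance anchor; PCA scores behave alike
  centers <- withSeed(seed, {
    pick <- function(cand, k, ranked = NULL) {
      sel <- integer(0)
      pool <- cand
      if (!is.null(ranked)) pool <- ranked[ranked %in% cand]
      while (length(sel) < k && length(pool) > 0L) {
        j <- if (is.null(ranked)) pool[sample.int(length(pool), 1L)] else
          pool[1L]
        sel <- c(sel, j)
        # keep later ROIs from overlapping this one
        r0 <- ((j - 1L) %% d[1L]) + 1L
        c0 <- ((j - 1L) %/% d[1L]) + 1L
        nearR <- abs(((pool - 1L) %% d[1L]) + 1L - r0) <= side
        nearC <- abs(((pool - 1L) %/% d[1L]) + 1L - c0) <= side
        pool <- pool[!(nearR & nearC)]
      }
      sel
    }
    candTop <- which(ok & matrix(topRows, d[1L], d[2L]))
    candSub <- which(ok & !matrix(topRows, d[1L], d[2L]))
    rankedHi <- candSub[order(score[candSub], decreasing = TRUE)]
    rankedLo <- candSub[order(score[candSub])]
    selHi <- pick(candSub, ceiling(nExtreme / 2), rankedHi)
    selLo <- pick(setdiff(candSub, selHi), floor(nExtreme / 2), rankedLo)
    selTop <- pick(candTop, nTop)
    used <- c(selHi, selLo)
    selSub <- pick(setdiff(candSub, used), n - nTop - length(used))
    c(selTop, selHi, selLo, selSub)
  })
  if (length(centers) < n)
    warning("placed only ", length(centers), " of ", n, " requested ROIs")
  noise <- withSeed(substreamSeed(seed, "roi_soc"),
                    stats::rnorm(length(centers), sd = measurementSD))
  rois <- vector("list", length(centers))
  for (i in seq_along(centers)) {
    r0 <- ((centers[i] - 1L) %% d[1L]) + 1L
    c0 <- ((centers[i] - 1L) %/% d[1L]) + 1L
    px <- as.matrix(expand.grid(row = (r0 - roiHalf):(r0 + roiHalf),
                                col = (c0 - roiHalf):(c0 + roiHalf)))
    soc <- max(0.1, mean(truthField[px]) + noise[i])
    rois[[i]] <- regionOfInterest(
      roiId = sprintf("%s_roi%02d", coreId, i), pixels = px,
      measuredSoc = soc, pixelSize = pixelSize(cube), coreId = coreId,
      depthOrigin = depthOrigin(cube),
      horizonBoundaryCm = horizonBoundaryCm)
  }
  rois
}
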