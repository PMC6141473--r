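#' Goodness-of-fit metrics for SOC predictions
#'
#' Computes the standard chemometric evaluation set: mean error
#' (ME = mean(predicted - measured), i.e. bias), root mean squared error
#' (RMSE), mean absolute error (MAE), residual prediction deviation
#' (RPD = sd(measured)/RMSE) and explained variance
#' (R2 = 1 - SSE/SStot). The sd in RPD uses the population (n)
#' denominator, so the identity \code{r2 == 1 - 1/rpd^2} holds exactly.
#' Perfect predictions give RMSE 0 and RPD infinite.
#'
#' @param measured,predicted numeric vectors of equal length >= 2.
#' @return one-row data.frame with columns me, rmse, mae, rpd, r2, n.
#' @export
#' @examples
#' computeMetrics(c(1, 2, 3), c(1.1, 1.9, 3.2))
computeMetrics <- function(measured, predicted) {
  if (length(measured) != length(predicted))
    stop("measured and predicted must have equal length")
  if (length(measured) < 2L) stop("need at least 2 observations")
  e <- predicted - measured
  me <- mean(e)
  rmse <- sqrt(mean(e^2))
  mae <- mean(abs(e))
  sdm <- popSD(measured)
  if (sdm == 0) {
    rpd <- NA_real_; r2 <- NA_real_
    warning("measured values have zero variance; RPD and R2 undefined")
  } else if (rmse == 0) {
    rpd <- Inf; r2 <- 1
  } else {
    rpd <- sdm / rmse
    r2 <- 1 - sum(e^2) / sum((measured - mean(measured))^2)
  }
  data.frame(me = me, rmse = rmse, mae = mae, rpd = rpd, r2 = r2,
             n = length(measured))
}

#' Distribution summary of a SOC map
#'
#' Order statistics and moments over the unmasked predictions, plus the
#' implausibility fractions: the proportion of predictions below zero and
#' the proportion above the highest SOC content of any calibrated sample.
#'
#' @param map a \linkS4class{SOCMap}.
#' @param upperLimit the calibration maximum (mg/g); default: the limit of
#'   the model that produced the map.
#' @return one-row data.frame with mean, median, maximum, minimum, sd,
#'   proportionBelowZero, proportionAboveUpper, n.
#' @export
summarizeDistribution <- function(map, upperLimit = NULL) {
  stopifnot(is(map, "SOCMap"))
  if (is.null(upperLimit)) upperLimit <- map@modelInfo$socMax
  stopifnot(is.finite(upperLimit))
  v <- socValues(map)[soilMask(map)]
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("map has no unmasked predictions")
  data.frame(mean = mean(v), median = stats::median(v), maximum = max(v),
             minimum = min(v), sd = stats::sd(v),
             proportionBelowZero = mean(v < 0),
             proportionAboveUpper = mean(v > upperLimit),
             n = length(v))
}

#' Evaluate a SOC map against bulk samples
#'
#' For each bulk depth interval the predicted value is the chosen statistic
#' (mean or median) of the unmasked map pixels in that slab. With
#' \code{band = 1} the effective prediction is the point of
#' \code{[stat - sd, stat + sd]} closest to the measured value, so a
#' measured value inside the one-sd envelope yields zero error — the
#' convention under which a predictor whose slab variance swamps the signal
#' scores a formally perfect fit, which is why the envelope variant must be
#' read together with the plain one.
#'
#' @param map a \linkS4class{SOCMap} covering the bulk intervals.
#' @param bulk data.frame with columns depthTop, depthBottom (cm) and soc
#'   (measured, mg/g).
#' @param statistic \code{"mean"} or \code{"median"}.
#' @param band 0 (point evaluation) or 1 (one-sd envelope).
#' @return list with \code{slabs} (per-interval table: measured, predicted
#'   statistic, slab sd, effective prediction, pixel count) and
#'   \code{metrics} (\code{\link{computeMetrics}} over the slabs). Slabs
#'   with zero unmasked pixels are excluded and listed in
#'   \code{excluded}.
#' @export
evaluateBulk <- function(map, bulk, statistic = c("mean", "median"),
                         band = 0) {
  statistic <- match.arg(statistic)
  stopifnot(is(map, "SOCMap"), band %in% c(0, 1),
            all(c("depthTop", "depthBottom", "soc") %in% names(bulk)))
  depths <- rowDepths(map)
  lo <- depthOrigin(map)
  hi <- lo + nrow(socValues(map)) * pixelSize(map) / 1e4
  if (min(bulk$depthTop) < lo - 1e-9 || max(bulk$depthBottom) > hi + 1e-9)
    stop("bulk intervals extend beyond the map depth range")
  v <- socValues(map)
  v[!soilMask(map)] <- NA
  stat <- sdv <- nPix <- numeric(nrow(bulk))
  for (i in seq_len(nrow(bulk))) {
    rows <- depths >= bulk$depthTop[i] & depths < bulk$depthBottom[i]
    px <- v[rows, , drop = FALSE]
    px <- px[!is.na(px)]
    nPix[i] <- length(px)
    if (length(px) > 0L) {
      stat[i] <- if (statistic == "mean") mean(px) else stats::median(px)
      sdv[i] <- if (length(px) > 1L) stats::sd(px) else 0
    }
  }
  keep <- nPix > 0L
  excluded <- bulk[!keep, c("depthTop", "depthBottom"), drop = FALSE]
  slabs <- data.frame(depthTop = bulk$depthTop[keep],
                      depthBottom = bulk$depthBottom[keep],
                      measured = bulk$soc[keep], predicted = stat[keep],
                      predictedSD = sdv[keep], nPixels = nPix[keep])
  slabs$effective <- if (band == 1)
    pmin(pmax(slabs$measured, slabs$predicted - slabs$predictedSD),
         slabs$predicted + slabs$predictedSD)
  else slabs$predicted
  list(slabs = slabs,
       metrics = if (nrow(slabs) >= 2L)
         computeMetrics(slabs$measured, slabs$effective) else NULL,
       statistic = statistic, band = band, excluded = excluded)
}

#' All four bulk-evaluation variants
#'
#' Runs \code{\link{evaluateBulk}} for mean, median, mean +/- 1 sd and
#' median +/- 1 sd and stacks the metrics into one table.
#'
#' @param map a \linkS4class{SOCMap}.
#' @param bulk bulk-sample table (see \code{\link{evaluateBulk}}).
#' @return data.frame of metrics, one row per variant.
#' @export
bulkEvaluationVariants <- function(map, bulk) {
  out <- do.call(rbind, lapply(
    list(c("mean", 0), c("median", 0), c("mean", 1), c("median", 1)),
    function(v) {
      ev <- evaluateBulk(map, bulk, statistic = v[[1L]],
                         band = as.numeric(v[[2L]]))
      cbind(variant = paste0(v[[1L]],
                             if (v[[2L]] == "1") " +/- 1 sd" else ""),
            ev$metrics)
    }))
  rownames(out) <- NULL
  out
}

#' Pooled bulk evaluation across several cores
#'
#' @param maps list of \linkS4class{SOCMap}, one per core.
#' @param bulks list of bulk tables matching \code{maps}.
#' @param statistic,band as in \code{\link{evaluateBulk}}.
#' @return list with the pooled \code{slabs} table (with a core column) and
#'   pooled \code{metrics}.
#' @export
evaluateBulkPooled <- function(maps, bulks, statistic = "mean", band = 0) {
  stopifnot(length(maps) == length(bulks), length(maps) >= 1L)
  tabs <- lapply(seq_along(maps), function(i) {
    ev <- evaluateBulk(maps[[i]], bulks[[i]], statistic = statistic,
                       band = band)
    cbind(core = i, ev$slabs)
  })
  slabs <- do.call(rbind, tabs)
  list(slabs = slabs,
       metrics = computeMetrics(slabs$measured, slabs$effective),
       statistic = statistic, band = band)
}

#' Residual diagnostics against SOC, depth and horizontal position
#'
#' Quantifies the structure that motivates the depth-stratified bias
#' correction: the slope of residuals against measured SOC (regression to
#' the mean gives a negative slope), the mean residual per horizon, and the
#' correlation of residuals with horizontal position (expected ~0).
#'
#' @param residuals data.frame with columns resid, soc, horizon and column.
#' @return list with socSlope (estimate, se), horizonMeans (named vector)
#'   and columnCorrelation.
#' @export
residualDepthDiagnostics <- function(residuals) {
  stopifnot(all(c("resid", "soc", "horizon", "column") %in%
                  names(residuals)))
  if (nrow(residuals) < 5L) stop("need at least 5 residuals")
  slope <- c(estimate = 0, se = NA_real_)
  if (stats::sd(residuals$soc) > 0) {
    fit <- stats::lm(resid ~ soc, data = residuals)
    slope <- c(estimate = unname(stats::coef(fit)[2L]),
               se = unname(sqrt(diag(stats::vcov(fit)))[2L]))
  }
  hm <- tapply(residuals$resid, residuals$horizon, mean)
  colCor <- if (stats::sd(residuals$column) > 0 &&
                stats::sd(residuals$resid) > 0)
    stats::cor(residuals$resid, residuals$column) else 0
  list(socSlope = slope, horizonMeans = hm, columnCorrelation = colCor)
}
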