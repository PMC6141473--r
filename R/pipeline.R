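#' Default pipeline configuration
#'
#' A plain list mirroring the YAML schema accepted by
#' \code{\link{readPipelineConfig}}. The synthetic block reproduces the
#' study design: five 1 m cores, three cut into 7 bulk depth increments
#' and two into 6 (33 bulk samples in all), 71 calibration ROIs placed
#' across the cores with a quarter in the plough horizon.
#'
#' @param seed global seed; every stage derives its own sub-stream from it.
#' @param outdir output directory.
#' @return a named list.
#' @export
defaultPipelineConfig <- function(seed = 1L, outdir = "socmap-output") {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    synthetic = list(nCores = 5L, schemes = c(7L, 7L, 7L, 6L, 6L),
                     pixelSize = 2500, crackFraction = 0.01),
    roi = list(nROIs = 71L, roiHalf = 1L, topsoilFraction = 0.25),
    masking = list(upperBandThreshold = 0.15, ratioBounds = c(1.5, 12)),
    treatments = c("normalized_reflectance", "snv"),
    models = c("pls", "rf", "svm"),
    svm = list(grid = NULL, cvFolds = 10L, bootstrapReps = 25L),
    pls = list(maxComponents = 20L, cvFolds = 5L),
    rf = list(nTrees = 200L, sampleFraction = 0.33),
    evaluation = list(windowHeightCm = 6),
    hotspots = list(enrichmentThreshold = 2, annulusRadiusCm = 1,
                    minRegionPx = 2L))
}

#' Read a pipeline configuration from YAML
#'
#' Missing keys fall back to \code{\link{defaultPipelineConfig}}.
#'
#' @param path YAML file path.
#' @return config list.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultPipelineConfig()
  mergeList <- function(base, over) {
    for (nm in names(over))
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        mergeList(base[[nm]], over[[nm]]) else over[[nm]]
    base
  }
  mergeList(cfg, user)
}

coreConfigFromPipeline <- function(config, i) {
  syntheticCoreConfig(
    pixelSize = config$synthetic$pixelSize %||% 2500,
    crackFraction = config$synthetic$crackFraction %||% 0.01,
    seed = substreamSeed(config$seed, paste0("core", i)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate the synthetic core set and write its files
#'
#' Writes, per core, the raw cube and target scan as ENVI rasters, the
#' truth SOC field and non-soil mask as single-band rasters, and pooled
#' bulk/ROI truth tables as CSV; a JSON manifest records the config, seeds
#' and file checksums.
#'
#' @param config a pipeline config list (see
#'   \code{\link{defaultPipelineConfig}}).
#' @return list with the \linkS4class{GroundTruthCore} objects and the
#'   manifest, invisibly.
#' @export
runSimulate <- function(config = defaultPipelineConfig()) {
  outdir <- config$outdir
  if (!dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
    message("created output directory ", outdir)
  }
  n <- config$synthetic$nCores
  schemes <- config$synthetic$schemes
  cores <- vector("list", n)
  bulkRows <- list()
  for (i in seq_len(n)) {
    cfg <- coreConfigFromPipeline(config, i)
    scheme <- if (schemes[i] == 7L) bulkScheme7() else bulkScheme6()
    cores[[i]] <- simulateCore(cfg, scheme)
    writeENVI(rawCube(cores[[i]]),
              file.path(outdir, sprintf("core%d_raw.dat", i)))
    writeENVI(socField(cores[[i]]),
              file.path(outdir, sprintf("core%d_truth.dat", i)))
    writeENVI(nonSoilMaskTruth(cores[[i]]),
              file.path(outdir, sprintf("core%d_nonsoil.dat", i)))
    tgt <- reflectanceTarget(cores[[i]])
    utils::write.csv(data.frame(column = seq_len(nrow(tgt@intensity)),
                                tgt@intensity),
                     file.path(outdir, sprintf("core%d_target.csv", i)),
                     row.names = FALSE)
    bulkRows[[i]] <- cbind(core_id = i, bulkTruth(cores[[i]]))
  }
  bulk <- do.call(rbind, bulkRows)
  utils::write.csv(bulk, file.path(outdir, "bulk_samples.csv"),
                   row.names = FALSE)
  manifest <- writeManifest(config, outdir, stage = "simulate")
  invisible(list(cores = cores, bulk = bulk, manifest = manifest))
}

writeManifest <- function(config, outdir, stage, timings = NULL) {
  files <- list.files(outdir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    stage = stage,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    package = as.character(utils::packageVersion("socmap")),
    seed = config$seed,
    config = config,
    timings = timings,
    outputs = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

#' Run the full analysis end to end
#'
#' Simulation, normalization, masking, SNV, ROI selection, calibration,
#' model fitting (PLS, RF, SVM), per-pixel prediction,
#' calibration-range-constrained PLS, bias-corrected RF, distribution
#' summaries, bulk evaluation in all four variants, depth profiles and
#' hotspot reports. All tabular outputs are written as CSV, maps as ENVI
#' rasters, a first-components false-colour rendering as PNG, and a
#' manifest as JSON.
#'
#' @param config a pipeline config list.
#' @return list with cores, calibration sets, fitted models, maps,
#'   evaluation tables, profiles and hotspot reports, invisibly.
#' @export
runFull <- function(config = defaultPipelineConfig()) {
  t0 <- Sys.time()
  timings <- list()
  tick <- function(name, expr) {
    s <- Sys.time()
    value <- force(expr)
    timings[[name]] <<- round(as.numeric(Sys.time() - s, units = "secs"), 2)
    value
  }
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  sim <- tick("simulate", runSimulate(config))
  cores <- sim$cores
  n <- length(cores)

  prep <- tick("preprocess", lapply(seq_len(n), function(i) {
    norm <- normalizeToTarget(rawCube(cores[[i]]),
                              reflectanceTarget(cores[[i]]))
    norm <- maskNonSoil(norm,
      upperBandThreshold = config$masking$upperBandThreshold,
      ratioBounds = config$masking$ratioBounds)
    list(nr = norm, snv = snvTransform(norm))
  }))
  message("masked fractions: ",
          paste(vapply(prep, function(p)
            sprintf("%.3f", 1 - mean(soilMask(p$nr))), ""), collapse = " "))

  pcaFirst <- pcaRGB(prep[[1L]]$nr)
  img <- pcaFirst$image
  img[is.na(img)] <- 0
  png::writePNG(img, file.path(outdir, "core1_pca_rgb.png"))

  roiPerCore <- diff(round(seq(0, config$roi$nROIs, length.out = n + 1L)))
  rois <- tick("rois", unlist(lapply(seq_len(n), function(i)
    selectROIsAuto(prep[[i]]$nr, socField(cores[[i]]),
                   n = roiPerCore[i], roiHalf = config$roi$roiHalf,
                   topsoilFraction = config$roi$topsoilFraction,
                   coreId = paste0("core", i),
                   measurementSD = cores[[i]]@config@socMeasurementSD,
                   seed = substreamSeed(config$seed, paste0("roi", i)))),
    recursive = FALSE))

  results <- list()
  for (tr in config$treatments) {
    trKey <- if (tr == "snv") "snv" else "nr"
    cubes <- stats::setNames(lapply(prep, `[[`, trKey),
                             paste0("core", seq_len(n)))
    cal <- buildCalibrationSet(rois, cubes,
                               seed = substreamSeed(config$seed, "cal"))
    models <- list()
    if ("pls" %in% config$models)
      models$pls <- fitPLS(cal, maxComponents = config$pls$maxComponents,
                           cvFolds = config$pls$cvFolds,
                           seed = substreamSeed(config$seed, "pls"))
    if ("rf" %in% config$models)
      models$rf <- fitRF(cal, nTrees = config$rf$nTrees,
                         sampleFraction = config$rf$sampleFraction,
                         seed = substreamSeed(config$seed, "rf"))
    if ("svm" %in% config$models)
      models$svm <- fitSVM(cal,
                           grid = config$svm$grid %||% defaultSVMGrid(),
                           cvFolds = config$svm$cvFolds,
                           bootstrapReps = config$svm$bootstrapReps,
                           seed = substreamSeed(config$seed, "svm"))
    for (m in names(models))
      message(tr, "/", m, ": ",
              paste(utils::head(names(hyperparameters(models[[m]])), 3L),
                    collapse = ","))
    maps <- list()
    for (m in names(models)) {
      maps[[m]] <- lapply(cubes, function(cb) predictMap(models[[m]], cb))
      if (m == "pls")
        maps$pls_constrained <- lapply(maps$pls, constrainPredictions)
      if (m == "rf") {
        bc <- estimateBiasCorrection(models$rf, cal,
          horizonBoundaryCm = horizonBoundary(cores[[1L]]))
        maps$rf_bias_corrected <- lapply(maps$rf, applyBiasCorrection,
                                         bc = bc)
        models$rf@biasCorrection <- bc
      }
    }
    upper <- unname(calibrationLimits(cal)["socMax"])
    bulks <- lapply(cores, bulkTruth)
    summaries <- do.call(rbind, lapply(names(maps), function(m) {
      pooled <- do.call(c, lapply(maps[[m]], function(mp)
        socValues(mp)[soilMask(mp)]))
      one <- SOCMap(matrix(pooled, ncol = 1L), pixelSize = 1,
                    modelInfo = list(socMax = upper))
      cbind(model = m, summarizeDistribution(one, upper))
    }))
    evals <- do.call(rbind, lapply(names(maps), function(m) {
      do.call(rbind, lapply(list(c("mean", 0), c("median", 0),
                                 c("mean", 1), c("median", 1)),
        function(v) {
          ev <- evaluateBulkPooled(maps[[m]], bulks, statistic = v[[1L]],
                                   band = as.numeric(v[[2L]]))
          cbind(model = m, variant = paste0(v[[1L]],
                  if (v[[2L]] == "1") " +/- 1 sd" else ""), ev$metrics)
        }))
    }))
    profiles <- hotspotTables <- list()
    profKey <- if ("rf_bias_corrected" %in% names(maps))
      "rf_bias_corrected" else names(maps)[1L]
    for (i in seq_len(n)) {
      profiles[[i]] <- cbind(core = i,
        depthProfile(maps[[profKey]][[i]],
                     windowHeightCm = config$evaluation$windowHeightCm))
      hs <- detectHotspots(maps[[profKey]][[i]],
        enrichmentThreshold = config$hotspots$enrichmentThreshold,
        annulusRadiusCm = config$hotspots$annulusRadiusCm,
        minRegionPx = config$hotspots$minRegionPx)
      hotspotTables[[i]] <- if (nrow(hs)) cbind(core = i, hs) else NULL
    }
    profiles <- do.call(rbind, profiles)
    hotspotTab <- do.call(rbind, hotspotTables)
    prefix <- file.path(outdir, tr)
    utils::write.csv(summaries, paste0(prefix, "_distribution_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(evals, paste0(prefix, "_bulk_evaluation.csv"),
                     row.names = FALSE)
    utils::write.csv(profiles, paste0(prefix, "_depth_profiles.csv"),
                     row.names = FALSE)
    if (!is.null(hotspotTab))
      utils::write.csv(hotspotTab, paste0(prefix, "_hotspots.csv"),
                       row.names = FALSE)
    for (m in names(maps)) for (i in seq_len(n))
      writeENVI(socValues(maps[[m]][[i]]),
                file.path(outdir, sprintf("%s_%s_core%d_map.dat", tr, m, i)))
    results[[tr]] <- list(calibration = cal, models = models, maps = maps,
                          summaries = summaries, evaluations = evals,
                          profiles = profiles, hotspots = hotspotTab)
  }
  timings$total <- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
  manifest <- writeManifest(config, outdir, stage = "full",
                            timings = timings)
  invisible(c(results, list(cores = cores, manifest = manifest)))
}
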