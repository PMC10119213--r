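#' Run the full quantification pipeline
#'
#' Orchestrates acquire (TIFF input or simulation), segment, zone
#' partitioning, quantification, SNR profiling and report writing as one
#' reproducible run driven by a single configuration (a nested list or a
#' YAML/JSON file path). Exactly one input mode must be set
#' (\code{input$tiff} or \code{input$simulate}). A single global seed derives
#' per-stage seeds by fixed offsets (optics seed + 1, treatment seed + 2/ +
#' 3, quadrant seed + 17) so stages are individually reproducible; every
#' effective parameter and seed is echoed into the run metadata.
#'
#' Configuration keys (all optional unless noted): \code{input$tiff} (path) or
#' \code{input$simulate} (list with \code{preset} and \code{\link{SimParams}}
#' overrides); \code{calibration} (\code{xy_size}, \code{z_step}; required
#' for TIFF input); \code{input$depth_offset}; \code{segmentation} (keys
#' matching \code{\link{SegmentationParams}} arguments in snake_case);
#' \code{zones$roi} (boundary file) or \code{zones$mode} ("truth" for
#' simulated scenes, "auto" for image-based estimation);
#' \code{quadrant$restrict_invasion} (default TRUE) and \code{quadrant$seed};
#' \code{mitoses} (annotation CSV path); \code{snr$threshold} and
#' \code{snr$background_region}; \code{time_label}; \code{seed} (required);
#' \code{out_dir} (required).
#'
#' @param config nested list or path to a YAML/JSON config file.
#' @return The manifest (named list of artifacts written), invisibly.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readConfig(config)
  if (is.null(config$seed)) sqStop("sqConfigError", "config$seed is required")
  if (is.null(config$out_dir)) sqStop("sqConfigError", "config$out_dir is required")
  seed <- config$seed
  hasTiff <- !is.null(config$input$tiff)
  hasSim <- !is.null(config$input$simulate)
  if (hasTiff == hasSim)
    sqStop("sqConfigError",
           "exactly one input mode must be set: input$tiff or input$simulate")
  stage <- "acquire"
  tryCatch({
    truth <- NULL; simParams <- NULL; treatment <- NULL
    if (hasTiff) {
      if (is.null(config$calibration))
        sqStop("sqConfigError", "calibration is required for TIFF input")
      cal <- PixelCalibration(config$calibration$xy_size,
                              config$calibration$z_step %||% 10)
      if (normalizePath(config$out_dir, mustWork = FALSE) ==
          normalizePath(dirname(config$input$tiff[1]), mustWork = FALSE))
        sqStop("sqConfigError", "out_dir must be distinct from the input directory")
      stack <- readStack(config$input$tiff[1], cal,
                         config$input$depth_offset %||% 0)
    } else {
      sim <- config$input$simulate
      ov <- sim$overrides %||% list()
      if (!is.null(config$calibration))
        ov$calibration <- PixelCalibration(config$calibration$xy_size,
                                           config$calibration$z_step %||% 10)
      simParams <- do.call(simPreset,
                           c(list(preset = sim$preset %||% "control", seed = seed), ov))
      treatment <- attr(simParams, "treatment")
      if (!is.null(treatment)) {
        pair <- do.call(simulateTreatmentPair, c(list(simParams), treatment))
        stack <- pair$treated$stack; truth <- pair$treated$truth
      } else {
        s <- simulateSpheroid(simParams)
        stack <- s$stack; truth <- s$truth
      }
      cal <- calibration(stack)
    }
    stage <- "segment"
    segArgs <- config$segmentation %||% list()
    names(segArgs) <- gsub("_(.)", "\\U\\1", names(segArgs), perl = TRUE)
    segParams <- do.call(SegmentationParams, segArgs)
    seg <- segmentStack(stack, segParams)
    stage <- "zones"
    if (!is.null(config$zones$roi)) {
      polys <- readBoundaries(config$zones$roi)
      labs <- vapply(polys, function(p) p@label, character(1))
      ells <- lapply(polys, fitBoundaryEllipse)
      names(ells) <- labs
      zm <- buildZoneMap(ells[["core_rim"]], ells[["rim_invasion"]],
                         dim(voxels(stack))[2:3])
    } else if (hasSim && (config$zones$mode %||% "truth") == "truth") {
      zm <- zoneMapFromRadii(simCentroidPx(simParams), simParams@coreRadius,
                             simParams@coreRadius + simParams@rimThickness,
                             dim(voxels(stack))[2:3], cal)
    } else {
      polys <- estimateBoundaries(stack)
      ells <- lapply(polys, fitBoundaryEllipse)
      names(ells) <- vapply(polys, function(p) p@label, character(1))
      zm <- buildZoneMap(ells[["core_rim"]], ells[["rim_invasion"]],
                         dim(voxels(stack))[2:3])
    }
    qseed <- config$quadrant$seed %||% (seed + 17)
    quad <- selectQuadrant(zm, qseed)
    restrict <- config$quadrant$restrict_invasion %||% TRUE
    stage <- "quantify"
    nuclei <- radialDistance(seg$nuclei, zm@centroid, cal)
    nuclei <- assignZones(nuclei, zm, quad, restrict)
    apo <- detectApoptosis(seg$fragments, cal)
    events <- assignZones(apo$events, zm, quad, restrict)
    mit <- NULL
    if (!is.null(config$mitoses)) {
      ann <- read.csv(config$mitoses)
      mit <- ingestMitoses(ann, zm, nuclei, cal)
    }
    stage <- "snr"
    snr <- depthProfile(stack, config$snr$background_region,
                        config$snr$threshold %||% 5)
    stage <- "report"
    effective <- list(seed = seed, quadrant_seed = qseed,
                      quadrant = quad@quadrant,
                      restrict_invasion_to_quadrant = restrict,
                      calibration = list(xy_size = cal@xySize, z_step = cal@zStep),
                      segmentation = list(gaussian_sigma = segParams@gaussianSigma,
                                          window_radius = segParams@windowRadius,
                                          k = segParams@k, r = segParams@r,
                                          p = segParams@p, q = segParams@q,
                                          median_radius = segParams@medianRadius,
                                          min_area = segParams@minArea,
                                          max_area = segParams@maxArea),
                      treatment = treatment,
                      input_mode = if (hasTiff) "tiff" else "simulate")
    result <- summarizeQuantification(nuclei, events, mit, zm, quad, cal,
                                      timeLabel = config$time_label %||% "",
                                      snr = snr, fragments = apo$fragments,
                                      params = effective)
    zsum <- zoneSummary(result)
    invRow <- zsum[zsum$zone == "invasion", ]
    result@params$metrics <- list(
      invasion_count = invRow$total_nuclei,
      death_frequency = invRow$death_frequency,
      max_distance = invasionSummary(result)$max_um)
    manifest <- writeResults(result, config$out_dir)
    if (hasSim) {
      stPath <- file.path(config$out_dir, "stack.tif")
      writeStack(ImageStack(round(voxels(stack)), cal, depthOffset(stack)), stPath)
      gtPath <- file.path(config$out_dir, "ground_truth_cells.csv")
      write.csv(truthCells(truth), gtPath, row.names = FALSE)
      manifest$files$stack <- stPath
      manifest$files$ground_truth <- gtPath
    }
    message("pipeline run complete: ", config$out_dir, " (seed ", seed, ")")
    invisible(manifest)
  }, spheroidquantError = function(e) {
    sqStop("sqPipelineError", "stage '", stage, "' failed: ", conditionMessage(e))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare two groups of pipeline runs
#'
#' Collects one metric per run from the run metadata of each manifest (or
#' output directory) and compares the two groups with
#' \code{\link{mannWhitney}}. The comparison is written as JSON next to the
#' first group's output when \code{out} is given.
#'
#' @param runsA,runsB manifests from \code{\link{runPipeline}}, output
#'   directory paths, or lists/vectors of either.
#' @param metric one of "invasion_count", "death_frequency", "max_distance".
#' @param labels group labels.
#' @param out optional path for a JSON report.
#' @return A \linkS4class{ComparisonResult}.
#' @export
compareRuns <- function(runsA, runsB, metric = "invasion_count",
                        labels = c("A", "B"), out = NULL) {
  collect <- function(runs) {
    if (is.list(runs) && !is.null(runs$files)) runs <- list(runs)
    if (is.character(runs)) runs <- as.list(runs)
    vapply(runs, function(r) {
      metaPath <- if (is.character(r)) file.path(r, "run_metadata.json")
        else r$files$metadata
      meta <- jsonlite::fromJSON(metaPath)
      m <- meta$parameters$metrics
      if (is.null(m[[metric]]))
        sqStop("sqParamError", "metric '", metric, "' not found; available: ",
               paste(names(m), collapse = ", "))
      as.numeric(m[[metric]])
    }, numeric(1))
  }
  a <- collect(runsA); b <- collect(runsB)
  res <- mannWhitney(a, b, labels)
  if (!is.null(out))
    jsonlite::write_json(list(metric = metric, labels = labels,
                              values = list(a, b), U = res@U,
                              p_value = res@pValue, method = res@method),
                         out, auto_unbox = TRUE, digits = NA)
  res
}
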