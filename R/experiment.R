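# Declarative experiment driver: a YAML config fully determines a run
# (phantom, tilt angles, dose mode, seeds, combination, ROI), so the
# standard phantom / skull-analogue / dose experiments are shipped config
# files rather than ad-hoc scripts.

#' Read and validate an experiment configuration
#'
#' @param x path to a YAML file, or an already-parsed list.
#' @return the validated config (a named list, class `tiltmarConfig`).
#' @export
readExperimentConfig <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  fail <- function(field, why)
    stop("config field '", field, "': ", why, call. = FALSE)
  if (is.null(cfg$version)) fail("version", "missing (expected 1)")
  if (is.null(cfg$phantom$type) ||
      !cfg$phantom$type %in% c("gammex", "dental"))
    fail("phantom.type", "must be 'gammex' or 'dental'")
  if (is.null(cfg$angles) || length(cfg$angles) < 1 ||
      anyDuplicated(cfg$angles))
    fail("angles", "must be a non-empty list of distinct degrees")
  cfg$phantom$n <- cfg$phantom$n %||% 256L
  cfg$phantom$spacing <- cfg$phantom$spacing %||% 0.13
  cfg$dose <- cfg$dose %||% list(mode = "full")
  if (!cfg$dose$mode %in% c("full", "split"))
    fail("dose.mode", "must be 'full' or 'split'")
  cfg$mAs <- cfg$mAs %||% 200
  cfg$tiltAxis <- cfg$tiltAxis %||% "vertical"
  if (!cfg$tiltAxis %in% c("vertical", "inplane"))
    fail("tiltAxis", "must be 'vertical' or 'inplane'")
  cfg$sliceSpacing <- cfg$sliceSpacing %||% 0.2
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$combine <- cfg$combine %||% list("median", "mean")
  if (!all(unlist(cfg$combine) %in% c("median", "mean")))
    fail("combine", "entries must be 'median' or 'mean'")
  cfg$refine <- isTRUE(cfg$refine)
  if (is.null(cfg$roi$type) || !cfg$roi$type %in% c("ring", "box"))
    fail("roi.type", "must be 'ring' or 'box'")
  if (is.null(cfg$roi[["c"]])) fail("roi.c", "assumed true HU is required")
  structure(cfg, class = "tiltmarConfig")
}

experimentPhantom <- function(cfg) {
  switch(cfg$phantom$type,
         gammex = makeGammexPhantom(n = cfg$phantom$n,
                                    spacing = cfg$phantom$spacing),
         dental = makeDentalPhantom(n = cfg$phantom$n,
                                    spacing = cfg$phantom$spacing))
}

experimentRoi <- function(cfg, v) {
  r <- cfg$roi
  if (r$type == "ring")
    ringRoi(v, center = as.numeric(unlist(r$center %||% c(0, 0, 0))),
            rInner = r$rInner %||% 0.8, rOuter = r$rOuter %||% 1.6,
            slab = r$slab %||% 0.7)
  else
    boxRoi(v, center = as.numeric(unlist(r$center)),
           extents = as.numeric(unlist(r$extents)))
}

#' Simulate the tilted series of an experiment
#'
#' `cmdSimulate` writes one DICOM series plus a plain-text transform file
#' per tilt angle; `runSimulation` returns them in memory. Runs are
#' deterministic given the config (seeds included), so identical configs
#' produce bit-identical outputs.
#'
#' @param cfg config (path or list, see [readExperimentConfig()]).
#' @param outDir output directory for `cmdSimulate`.
#' @return `runSimulation`: the list from [simulateTiltedSeries()];
#'   `cmdSimulate`: invisibly, the output directory.
#' @export
runSimulation <- function(cfg) {
  cfg <- readExperimentConfig(cfg)
  p <- experimentPhantom(cfg)
  acq <- acquisitionConfig(mAs = cfg$mAs, noiseSeed = cfg$seed,
                           nDetectors = as.integer(ceiling(
                             cfg$phantom$n * sqrt(2))) + 1L,
                           detSpacing = cfg$phantom$spacing)
  cov <- roiCoverage(cfg)
  simulateTiltedSeries(p, as.numeric(unlist(cfg$angles)), acq,
                       tiltAxis = cfg$tiltAxis,
                       nSlices = cfg$nSlices,
                       sliceSpacing = cfg$sliceSpacing,
                       focus = cov$center,
                       coverRadius = cov$radius, coverHalfZ = cov$halfZ,
                       doseMode = cfg$dose$mode,
                       outSpacing = cfg$phantom$spacing,
                       outDim = cfg$phantom$n)
}

# Lab-frame region that must stay covered after registration, derived from
# the evaluation ROI, plus the common output mesh built around it.
roiCoverage <- function(cfg) {
  r <- cfg$roi
  center <- as.numeric(unlist(r$center %||% c(0, 0, 0)))
  if (r$type == "ring") {
    radius <- (r$rOuter %||% 1.6) + 0.3
    halfZ <- (r$slab %||% 0.7) / 2 + 0.15
  } else {
    ext <- as.numeric(unlist(r$extents))
    radius <- ext[1] / 2 + 0.3
    halfZ <- ext[3] / 2 + 0.15
  }
  list(center = center, radius = radius, halfZ = halfZ)
}

outputMesh <- function(cfg) {
  cov <- roiCoverage(cfg)
  n <- cfg$phantom$n; px <- cfg$phantom$spacing
  zsp <- cfg$mesh$zSpacing %||% 0.1
  nz <- 2L * as.integer(ceiling((cov$halfZ - 0.1) / zsp)) + 1L
  gridSpec(c(n, n, nz), c(px, px, zsp),
           origin = c(-(n - 1) / 2 * px, -(n - 1) / 2 * px,
                      cov$center[3] - (nz - 1) / 2 * zsp))
}

#' @rdname runSimulation
#' @export
cmdSimulate <- function(cfg, outDir) {
  cfg <- readExperimentConfig(cfg)
  series <- runSimulation(cfg)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  for (i in seq_along(series)) {
    d <- file.path(outDir, sprintf("scan_%02d", i))
    writeDicomSeries(series[[i]]$volume, d,
                     seriesUID = paste0(UID_ROOT, ".", cfg$seed, ".", i))
    writeTransform(series[[i]]$transform,
                   file.path(outDir, sprintf("transform_%02d.txt", i)))
  }
  message(length(series), " series written to ", outDir)
  invisible(outDir)
}

registerSeries <- function(volumes, transforms, target = NULL,
                           refine = FALSE) {
  target <- target %||% gridSpec(dim(volumes[[1]]), volumes[[1]]@spacing,
                                 volumes[[1]]@origin)
  lapply(seq_along(volumes), function(i) {
    reg <- resample(volumes[[i]], transforms[[i]], target)
    if (refine && i > 1L) {
      shift <- tryCatch(
        refineTranslation(reg, resample(volumes[[1]], transforms[[1]],
                                        target), axes = 1:2),
        error = function(e) rigidTransform())
      reg <- resample(reg, shift, target)
    }
    reg
  })
}

#' Full register / combine / evaluate pipeline
#'
#' `runPipeline` takes simulated scans in memory; `cmdPipeline` reads the
#' DICOM series and transform files written by [cmdSimulate()]. Each scan
#' is rigidly resampled into the common laboratory mesh, single-scan
#' metrics are computed, the incremental combinations for k = 1..n scans
#' are fused by each requested method, and all ROI metrics are returned as
#' one table (with n, c, method and seed recorded for provenance).
#'
#' @param cfg config (path or list).
#' @param series list as from [runSimulation()].
#' @return list with elements `report` (data.frame), `combined` (named list
#'   of final [CombinedVolume-class]), `registered` (list of volumes).
#' @export
runPipeline <- function(cfg, series) {
  cfg <- readExperimentConfig(cfg)
  volumes <- lapply(series, `[[`, "volume")
  transforms <- lapply(series, `[[`, "transform")
  registered <- registerSeries(volumes, transforms, target = outputMesh(cfg),
                               refine = cfg$refine)
  roi <- experimentRoi(cfg, registered[[1]])
  cTrue <- cfg$roi[["c"]]
  rows <- list()
  for (i in seq_along(registered)) {
    m <- evaluateRoi(registered[[i]], roi, c = cTrue)
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(method = "single", k = i), m,
            data.frame(seed = cfg$seed))
  }
  combined <- list()
  for (method in unlist(cfg$combine)) {
    inc <- incrementalSeries(registered, method)
    for (k in seq_along(inc)) {
      m <- evaluateRoi(inc[[k]], roi, c = cTrue)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(method = method, k = k), m,
              data.frame(seed = cfg$seed))
    }
    combined[[method]] <- inc[[length(inc)]]
  }
  list(report = do.call(rbind, rows), combined = combined,
       registered = registered)
}

#' @rdname runPipeline
#' @param inDir directory holding `scan_*/` series and `transform_*.txt`
#'   files.
#' @param outDir where to write the combined DICOM series and `report.csv`.
#' @export
cmdPipeline <- function(cfg, inDir, outDir) {
  cfg <- readExperimentConfig(cfg)
  scanDirs <- sort(list.dirs(inDir, recursive = FALSE))
  scanDirs <- scanDirs[grepl("scan_\\d+$", scanDirs)]
  if (length(scanDirs) == 0L) stop("no scan_* series under ", inDir)
  series <- lapply(seq_along(scanDirs), function(i) {
    list(volume = readDicomSeries(scanDirs[i]),
         transform = readTransform(
           file.path(inDir, sprintf("transform_%02d.txt", i))))
  })
  res <- runPipeline(cfg, series)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  for (method in names(res$combined)) {
    cv <- res$combined[[method]]
    writeDicomSeries(requireCoverage(cv, 1L),
                     file.path(outDir, paste0("combined_", method)),
                     seriesUID = paste0(UID_ROOT, ".", cfg$seed, ".9",
                                        match(method, names(res$combined))))
  }
  write.csv(res$report, file.path(outDir, "report.csv"), row.names = FALSE)
  invisible(res$report)
}
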