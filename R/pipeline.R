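#' @include AllClasses.R preprocess.R firstorder-stats.R patch-stats.R secondorder-stats.R compare-report.R
NULL

#' Pipeline configuration
#'
#' All printed analysis constants live in one config object; no stage
#' hard-codes them. Defaults: LoG scales 5/10/20/40 px, patch radius 30 px,
#' histogram bin 0.01, pixel pitch 0.006 degrees/px, 64 entropy bins,
#' representative autocorrelation offsets (0,50) and (50,0), significance
#' level 0.05.
#'
#' @param sigmaList LoG standard deviations (pixels).
#' @param patchRadiusPx circular patch radius (pixels).
#' @param histogramBin intensity histogram bin width.
#' @param pixelPitchDeg angular pixel pitch (degrees/pixel).
#' @param entropyBins entropy histogram bins.
#' @param acfOffsets list of c(dH, dV) displacements.
#' @param significanceLevel alpha for star annotation.
#' @param patchStride centre-grid stride for patch maps.
#' @param seed RNG seed for any stochastic stage.
#' @return list of class "PipelineConfig" with a \code{hash} field
#'   identifying the configuration.
#' @export
pipelineConfig <- function(sigmaList = c(5, 10, 20, 40), patchRadiusPx = 30,
                           histogramBin = 0.01, pixelPitchDeg = 0.006,
                           entropyBins = 64, acfOffsets = list(c(0, 50), c(50, 0)),
                           significanceLevel = 0.05, patchStride = 1L,
                           seed = 1L) {
  # canonical storage modes so the config hash is stable across serialization
  cfg <- list(sigmaList = as.numeric(sigmaList),
              patchRadiusPx = as.numeric(patchRadiusPx),
              histogramBin = as.numeric(histogramBin),
              pixelPitchDeg = as.numeric(pixelPitchDeg),
              entropyBins = as.integer(entropyBins),
              acfOffsets = lapply(acfOffsets, as.numeric),
              significanceLevel = as.numeric(significanceLevel),
              patchStride = as.integer(patchStride), seed = as.integer(seed))
  cfg$hash <- digest::digest(cfg, algo = "crc32")
  structure(cfg, class = "PipelineConfig")
}

#' Serialize / restore a pipeline configuration
#'
#' Round-trips losslessly through JSON.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param path JSON file path.
#' @return \code{readPipelineConfig}: a "PipelineConfig".
#' @export
writePipelineConfig <- function(config, path) {
  jsonlite::write_json(unclass(config)[setdiff(names(config), "hash")], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$acfOffsets <- lapply(seq_len(nrow(x$acfOffsets)), function(i) x$acfOffsets[i, ])
  do.call(pipelineConfig, x)
}

#' Read a scene pair and its metadata from disk
#'
#' Expects \code{<stem>_uv.png}, \code{<stem>_green.png} and (optionally)
#' \code{<stem>_ref.png} as 16-bit grayscale PNGs under \code{root}, plus a
#' metadata row keyed by stem in \code{root/scenes.csv}.
#'
#' @param stem scene identifier.
#' @param root directory holding the PNGs and scenes.csv.
#' @return list with \code{rawUv}, \code{rawGreen}, \code{reference} (NULL
#'   when absent) and \code{metadata} (a \linkS4class{SceneMetadata}).
#' @export
readScenePair <- function(stem, root) {
  fUv <- file.path(root, paste0(stem, "_uv.png"))
  fGr <- file.path(root, paste0(stem, "_green.png"))
  fRef <- file.path(root, paste0(stem, "_ref.png"))
  if (!file.exists(fUv) || !file.exists(fGr))
    stop("missing channel PNG for stem '", stem, "' under ", root)
  meta <- utils::read.csv(file.path(root, "scenes.csv"),
                          stringsAsFactors = FALSE)
  row <- meta[meta$stem == stem, , drop = FALSE]
  if (nrow(row) != 1)
    stop("scenes.csv has ", nrow(row), " rows for stem '", stem, "'")
  md <- new("SceneMetadata", stem = stem, elevation = row$elevation,
            exposureS = row$exposure_s, ndOd = row$nd_od,
            weather = as.character(row$weather),
            distance = as.character(row$distance),
            objects = as.character(row$objects))
  list(rawUv = readPNG16(fUv), rawGreen = readPNG16(fGr),
       reference = if (file.exists(fRef)) readPNG16(fRef) else NULL,
       metadata = md)
}

#' Per-scene statistic bundle
#'
#' Normalizes the pair and computes every per-scene parameter of the
#' analysis: per-channel, per-sigma Weibull contrast fits; per-channel
#' median RMS contrast; left/right chromatic Weibull fits; per-channel,
#' per-direction power-law fits; and the representative autocorrelation
#' values. Returned in long format ready for \code{\link{buildParamTable}}.
#'
#' @param pair a \linkS4class{ScenePair} (normalized or not; normalization
#'   is applied here).
#' @param config a \code{\link{pipelineConfig}}.
#' @return data.frame with columns scene, category, channel, parameter,
#'   value, config_hash.
#' @export
computeSceneStats <- function(pair, config = pipelineConfig()) {
  if (!pair@normalized) pair <- normalizeMinmax(pair)
  stem <- pair@metadata@stem
  catg <- pair@metadata@elevation
  rows <- list()
  addRow <- function(channel, parameter, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      scene = stem, category = catg, channel = channel,
      parameter = parameter, value = value, stringsAsFactors = FALSE)
  }
  chans <- list(UV = pair@uv, Green = pair@green)
  # first-order: LoG contrast Weibull fits per scale
  wb <- contrastWeibullPerScene(pair, config$sigmaList)
  for (i in seq_len(nrow(wb))) {
    addRow(wb$channel[i], paste0("weibull_beta_s", wb$sigma[i]), wb$beta_scale[i])
    addRow(wb$channel[i], paste0("weibull_gamma_s", wb$sigma[i]), wb$gamma_shape[i])
  }
  # patch stats: RMS contrast maps and chromatic contrast
  maps <- lapply(chans, function(img) {
    circularPatchStats(img, config$patchRadiusPx, "rms_contrast",
                       stride = config$patchStride)
  })
  for (ch in names(maps))
    addRow(ch, "rms_contrast_median",
           stats::median(maps[[ch]]$values, na.rm = TRUE))
  cmap <- chromaticContrast(maps$UV, maps$Green)
  cw <- fitChromaticWeibull(cmap)
  if (!is.null(cw$left)) {
    addRow("left", "chrom_beta", cw$left@betaScale)
    addRow("left", "chrom_gamma", cw$left@gammaShape)
  }
  if (!is.null(cw$right)) {
    addRow("right", "chrom_beta", cw$right@betaScale)
    addRow("right", "chrom_gamma", cw$right@gammaShape)
  }
  # second-order: power-law fits and representative autocorrelation values
  for (ch in names(chans)) {
    img <- chans[[ch]]
    img[!pair@valid] <- mean(img[pair@valid])
    sl <- axisSlices(powerSpectrum(img))
    fh <- fitPowerLaw(sl$horizontal)
    fv <- fitPowerLaw(sl$vertical)
    addRow(ch, "powerlaw_a_h", fh@slopeA)
    addRow(ch, "powerlaw_b_h", fh@interceptB)
    addRow(ch, "powerlaw_a_v", fv@slopeA)
    addRow(ch, "powerlaw_b_v", fv@interceptB)
    acf <- autocorrelation(img)
    for (o in config$acfOffsets)
      addRow(ch, sprintf("acf_%d_%d", o[1], o[2]),
             correlationAt(acf, o[1], o[2]))
  }
  out <- do.call(rbind, rows)
  out$config_hash <- config$hash
  out
}

#' Run the full analysis pipeline over a scene list
#'
#' Per scene: read, preprocess (vignetting correction when a reference is
#' present, median filter, registration, crop), compute statistics; then
#' build the parameter table and run the channel comparisons. Per-scene
#' failures are logged and skipped; the run fails only if every scene fails.
#' A JSON-lines event log records every exclusion so the accounting is
#' machine-checkable.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param sceneStems character vector of stems under \code{root}.
#' @param root input directory (PNGs + scenes.csv).
#' @param outDir output directory; receives results.csv, comparisons.csv,
#'   report.md, events.jsonl.
#' @param homographies optional named list of per-stem 3x3 matrices (UV to
#'   green); identity when absent.
#' @param cropRects optional named list of per-stem crop rectangles.
#' @return invisibly, a list with \code{stats} (long data.frame),
#'   \code{comparisons} and \code{failed} (stems).
#' @export
runPipeline <- function(config, sceneStems, root, outDir,
                        homographies = NULL, cropRects = NULL) {
  if (length(sceneStems) < 1) stop("need at least one scene")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logCon <- file(file.path(outDir, "events.jsonl"), "w")
  on.exit(close(logCon))
  logEvent <- function(scene, stage, event, ...) {
    writeLines(jsonlite::toJSON(
      c(list(scene = scene, stage = stage, event = event), list(...)),
      auto_unbox = TRUE), logCon)
  }
  allStats <- list(); failed <- character()
  for (stem in sceneStems) {
    res <- tryCatch({
      sc <- readScenePair(stem, root)
      h <- if (!is.null(homographies[[stem]])) homographies[[stem]] else diag(3)
      rect <- cropRects[[stem]]
      ref <- sc$reference
      pair <- if (!is.null(ref)) {
        preprocessScene(sc$rawUv, sc$rawGreen, ref, h, rect, sc$metadata,
                        config$pixelPitchDeg)
      } else {
        logEvent(stem, "preprocess", "no_reference_skipping_flatfield")
        cUv <- medianFilter3x3(sc$rawUv)
        cGr <- medianFilter3x3(sc$rawGreen)
        reg <- registerPair(cUv, cGr, h)
        p <- scenePair(reg$uv, reg$green, sc$metadata, config$pixelPitchDeg,
                       valid = reg$valid)
        if (!is.null(rect)) cropPair(p, rect) else p
      }
      st <- computeSceneStats(pair, config)
      logEvent(stem, "stats", "ok", rows = nrow(st))
      st
    }, error = function(e) {
      logEvent(stem, "scene", "failed", message = conditionMessage(e))
      NULL
    })
    if (is.null(res)) failed <- c(failed, stem) else
      allStats[[length(allStats) + 1L]] <- res
  }
  if (!length(allStats)) stop("all scenes failed")
  stats <- do.call(rbind, allStats)
  utils::write.csv(stats, file.path(outDir, "results.csv"), row.names = FALSE)
  tab <- buildParamTable(stats)
  logEvent("", "compare", "horizontal_excluded", n = attr(tab, "nExcluded"))
  cmp <- runComparisons(tab, defaultComparisonPlan(config$sigmaList))
  utils::write.csv(cmp, file.path(outDir, "comparisons.csv"), row.names = FALSE)
  writeComparisonReport(cmp, file.path(outDir, "report.md"))
  invisible(list(stats = stats, comparisons = cmp, failed = failed))
}

#' Export a statistic map as 32-bit float TIFF
#'
#' Writes a patch-statistic map, power spectrum or autocorrelation map as a
#' single-channel 32-bit float TIFF (requires the \pkg{tiff} package).
#' NA entries (invalid centres) are written as NaN.
#'
#' @param values numeric matrix.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeFloatMap <- function(values, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for float TIFF export")
  tiff::writeTIFF(values, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}
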