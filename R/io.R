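# Configuration, file I/O, fixture generation and the end-to-end pipeline
# driver. Stacks travel as multi-page TIFF with a JSON grid-metadata
# sidecar; tables as plain CSV (comma separated, header row, '.' decimal,
# UTF-8); scenario files as YAML.

#' Write / read a frame stack as multi-page TIFF with a metadata sidecar
#'
#' Intensities are stored as 32-bit float TIFF pages scaled into `[0, 1)` by
#' the recorded `scale`; the sidecar JSON carries the grid metadata needed
#' to reconstruct the [FrameStack-class].
#'
#' @param stack a [FrameStack-class].
#' @param path output TIFF path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
writeFrameStack <- function(stack, path) {
  dat <- stack@data
  mx <- max(dat, 1e-12)
  pages <- lapply(seq_len(dim(dat)[1]), function(t) dat[t, , ] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  cfg <- stack@config
  meta <- list(scale = mx, stage = stack@stage,
               soundSpeed = cfg@soundSpeed,
               centerFrequency = cfg@centerFrequency,
               frameRate = cfg@frameRate, finePixelUm = cfg@finePixelUm,
               downsample = cfg@downsample, fovFine = cfg@fovFine)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeFrameStack
#' @param path TIFF path written by [writeFrameStack()].
#' @export
readFrameStack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  dat <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (t in seq_along(pages)) dat[t, , ] <- pages[[t]] * meta$scale
  cfg <- imagingConfig(meta$soundSpeed, meta$centerFrequency, meta$frameRate,
                       meta$finePixelUm, meta$downsample, meta$fovFine)
  frameStack(dat, cfg, meta$stage)
}

#' Write / read localization tables
#'
#' Plain CSV with a header row; numeric columns keep full precision.
#'
#' @param det data.frame of detections or tracks.
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
writeDetections <- function(det, path) {
  write.csv(det, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeDetections
#' @export
readDetections <- function(path) read.csv(path)

configDefaults <- function() {
  list(
    soundSpeed = 1540, centerFrequency = 20e6, frameRate = 1000,
    finePixelUm = 12.3, downsample = 2L, fovFine = c(80L, 80L),
    concentration = 0.1, nFrames = 60L,
    speedRange = SPEED_RANGE_MM_S, lifetimeRange = LIFETIME_RANGE,
    perturbSd = 0.2,
    bankSource = "gaussian", bankSize = 50L, templateSide = 25L,
    templateSigmaRange = c(1.6, 2.4), muImax = 1, sigmaImax = 0.25,
    noiseSigmaFrac = 0.1,
    nccThreshold = 0.6, minDistance = 3L,
    pThresh = 0.6, uncertaintyRejectFrac = 0.05,
    maxGap = 2L, maxAngle = 45, minPersistence = 10L,
    seed = 1L
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML scenario file, fills defaults (bubble speed 5-25 mm/s,
#' lifetime 1-20 frames, direction perturbation SD 0.2, and the grid /
#' bank / localization / tracking defaults), and rejects unknown keys with
#' a suggestion for the closest valid name.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @return named list of validated configuration values, with an
#'   `imagingConfig` entry assembled from the grid fields.
#' @export
loadConfig <- function(path = NULL) {
  defs <- configDefaults()
  usr <- if (is.null(path)) list() else yaml::read_yaml(path)
  unknown <- setdiff(names(usr), names(defs))
  if (length(unknown)) {
    sugg <- vapply(unknown, function(k) {
      dd <- adist(k, names(defs))
      names(defs)[which.min(dd)]
    }, character(1))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(sprintf("'%s' (did you mean '%s'?)", unknown, sugg),
                       collapse = ", ")), call. = FALSE)
  }
  cfg <- utils::modifyList(defs, usr)
  for (key in c("soundSpeed", "centerFrequency", "frameRate", "finePixelUm",
                "concentration"))
    stopIfNot(is.numeric(cfg[[key]]) && cfg[[key]] > 0,
              paste(key, "must be a positive number"))
  cfg$imagingConfig <- imagingConfig(cfg$soundSpeed, cfg$centerFrequency,
                                     cfg$frameRate, cfg$finePixelUm,
                                     cfg$downsample, cfg$fovFine)
  cfg
}

#' Save a configuration back to YAML
#'
#' @param cfg configuration list from [loadConfig()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
saveConfig <- function(cfg, path) {
  cfg$imagingConfig <- NULL
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Generate self-contained benchmark fixtures
#'
#' `tiny`: a 32 x 32 fine grid, 60 frames, about 3 bubbles per frame --
#' sized for continuous-integration runs. `desk`: a 100 x 100 fine grid,
#' 500 frames at a sweep of concentrations -- the scaled benchmark
#' protocol. Both write TIFF stacks and ground-truth CSVs
#' (`frame,id,row_fine,col_fine,brightness`).
#'
#' @param profile "tiny" or "desk".
#' @param dir output directory (created if missing).
#' @param seed integer seed.
#' @param nFrames optional frame-count override.
#' @return invisible list of written paths.
#' @export
makeFixtures <- function(profile = c("tiny", "desk"), dir = tempfile("fix"),
                         seed = 1L, nFrames = NULL) {
  profile <- match.arg(profile)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (profile == "tiny") {
    cfg <- imagingConfig(fovFine = c(32L, 32L))
    concs <- 3 / fovAreaLambda2(cfg)
    nf <- if (is.null(nFrames)) 60L else nFrames
  } else {
    cfg <- imagingConfig(fovFine = c(100L, 100L))
    concs <- c(0.05, 0.15, 0.3)
    nf <- if (is.null(nFrames)) 500L else nFrames
  }
  bank <- gaussianTemplateBank(20, side = 13L, seed = deriveSeed(seed, "bank"))
  nm <- noiseModel(0.1 * bank@muImax, cfg@fovFine / cfg@downsample)
  paths <- list()
  for (i in seq_along(concs)) {
    sim <- simulateSequence(cfg, bank, nm, nf, concs[i],
                            seed = deriveSeed(seed, paste0("fix", i)))
    sp <- file.path(dir, sprintf("%s_c%02d.tif", profile, i))
    gp <- file.path(dir, sprintf("%s_c%02d_gt.csv", profile, i))
    writeFrameStack(sim$stack, sp)
    gt <- sim$gt
    names(gt) <- c("frame", "id", "row_fine", "col_fine", "brightness")
    writeDetections(gt, gp)
    paths[[length(paths) + 1L]] <- c(stack = sp, gt = gp)
  }
  invisible(paths)
}

#' Run the pipeline end to end
#'
#' Simulates (or loads) a stack, preprocesses, localizes (NCC baseline or a
#' supplied trained network), tracks, reconstructs, and optionally evaluates
#' against ground truth. A provenance record (configuration, seed, package
#' version) is written beside the outputs.
#'
#' @param cfg configuration list from [loadConfig()].
#' @param outputDir directory for artifacts.
#' @param method "ncc" or "decode".
#' @param model trained [DecodeModel-class] (required for "decode").
#' @param stack optional pre-made [FrameStack-class]; when NULL a stack is
#'   simulated from the configuration.
#' @param gt optional ground-truth data.frame for evaluation.
#' @return invisible list with `detections`, `tracks`, `density`, and (when
#'   ground truth is available) `evaluation`.
#' @export
pipelineRun <- function(cfg, outputDir = tempfile("ulm"), method = c("ncc", "decode"),
                        model = NULL, stack = NULL, gt = NULL) {
  method <- match.arg(method)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  ic <- cfg$imagingConfig
  bank <- gaussianTemplateBank(cfg$bankSize, cfg$templateSigmaRange,
                               cfg$templateSide, cfg$muImax, cfg$sigmaImax,
                               seed = deriveSeed(cfg$seed, "bank"))
  if (is.null(stack)) {
    nm <- noiseModel(cfg$noiseSigmaFrac * cfg$muImax,
                     ic@fovFine / ic@downsample)
    sim <- simulateSequence(ic, bank, nm, cfg$nFrames, cfg$concentration,
                            seed = deriveSeed(cfg$seed, "sim"))
    stack <- sim$stack
    if (is.null(gt)) gt <- sim$gt
  }
  det <- if (method == "ncc") {
    nccLocalize(stack, nccThreshold = cfg$nccThreshold,
                minDistance = cfg$minDistance)
  } else {
    stopIfNot(!is.null(model), "decode method needs a trained model")
    decodeLocalize(model, stack, pThresh = cfg$pThresh,
                   uncertaintyRejectFrac = cfg$uncertaintyRejectFrac)
  }
  writeDetections(det, file.path(outputDir, "detections.csv"))
  trk <- trackLocalizations(det, ic, maxGap = cfg$maxGap,
                            maxAngle = cfg$maxAngle,
                            minPersistence = cfg$minPersistence)
  writeDetections(trk, file.path(outputDir, "tracks.csv"))
  dens <- accumulateDensity(trk, ic)
  utils::write.table(dens, file.path(outputDir, "density.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  res <- list(detections = det, tracks = trk, density = dens)
  if (!is.null(gt) && nrow(gt) > 0) {
    radius <- matchRadiusPx(ic)
    frames <- sort(unique(gt$frame))
    per <- t(vapply(frames, function(t) {
      p <- det[det$frame == t, , drop = FALSE]
      g <- gt[gt$frame == t, , drop = FALSE]
      m <- matchLocalizations(p, g, radius)
      c(detectionAccuracy(m), missRate(m), localizationError(m, p, g))
    }, numeric(3)))
    res$evaluation <- data.frame(
      accuracy = mean(per[, 1], na.rm = TRUE),
      miss = mean(per[, 2], na.rm = TRUE),
      error = mean(per[, 3], na.rm = TRUE)
    )
    writeDetections(res$evaluation, file.path(outputDir, "evaluation.csv"))
  }
  prov <- list(config = cfg[setdiff(names(cfg), "imagingConfig")],
               method = method,
               package = as.character(utils::packageVersion("ulmloc")),
               rversion = R.version.string)
  jsonlite::write_json(prov, file.path(outputDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
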