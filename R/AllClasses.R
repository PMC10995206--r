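# S4 containers for the pipeline. Coordinates are (row = axial, col =
# lateral), 0-based, with pixel centres at integers; ground-truth positions
# live on the fine simulation grid unless stated otherwise.

#' ImagingConfig: acquisition and grid geometry
#'
#' Holds the acoustic and grid parameters every stage needs: speed of sound,
#' transmit centre frequency, frame rate, the fine (ground-truth) pixel size,
#' the integer downsampling factor between the fine grid and the network
#' input grid, and the fine-grid field of view. The acoustic wavelength
#' (micrometres) is derived as `soundSpeed / centerFrequency * 1e6`.
#'
#' @slot soundSpeed speed of sound in m/s.
#' @slot centerFrequency transmit centre frequency in Hz.
#' @slot frameRate post-compounding frame rate in Hz.
#' @slot finePixelUm fine-grid pixel size in micrometres.
#' @slot downsample integer factor between fine and input grids.
#' @slot fovFine integer (rows, cols) of the fine grid.
#' @slot wavelengthUm derived acoustic wavelength in micrometres.
#' @exportClass ImagingConfig
setClass("ImagingConfig",
  representation(
    soundSpeed = "numeric", centerFrequency = "numeric",
    frameRate = "numeric", finePixelUm = "numeric",
    downsample = "integer", fovFine = "integer", wavelengthUm = "numeric"
  )
)

setValidity("ImagingConfig", function(object) {
  msgs <- character()
  for (s in c("soundSpeed", "centerFrequency", "frameRate", "finePixelUm"))
    if (length(slot(object, s)) != 1 || slot(object, s) <= 0)
      msgs <- c(msgs, paste0(s, " must be a positive scalar"))
  if (length(object@downsample) != 1 || object@downsample < 1)
    msgs <- c(msgs, "downsample must be a positive integer")
  if (length(object@fovFine) != 2 || any(object@fovFine < 1))
    msgs <- c(msgs, "fovFine must be two positive integers")
  if (length(msgs)) msgs else TRUE
})

#' Construct an imaging configuration
#'
#' Defaults describe the chicken-embryo membrane style bench configuration
#' used throughout the synthetic studies: 20 MHz centre frequency (wavelength
#' 77 um), 1 kHz frame rate, 12.3 um fine pixels, an 80 x 80 fine grid
#' rendered and block-averaged by 2 into 40 x 40 network input frames.
#'
#' @param soundSpeed speed of sound (m/s).
#' @param centerFrequency transmit centre frequency (Hz).
#' @param frameRate frame rate (Hz).
#' @param finePixelUm fine-grid pixel size (micrometres).
#' @param downsample integer fine-to-input downsampling factor.
#' @param fovFine integer vector (rows, cols) of the fine grid.
#' @return an [ImagingConfig-class] object.
#' @examples
#' cfg <- imagingConfig()
#' wavelengthUm(cfg)  # 77 um at 20 MHz in 1540 m/s medium
#' @export
imagingConfig <- function(soundSpeed = 1540, centerFrequency = 20e6,
                          frameRate = 1000, finePixelUm = 12.3,
                          downsample = 2L, fovFine = c(80L, 80L)) {
  new("ImagingConfig",
    soundSpeed = soundSpeed, centerFrequency = centerFrequency,
    frameRate = frameRate, finePixelUm = finePixelUm,
    downsample = as.integer(downsample), fovFine = as.integer(fovFine),
    wavelengthUm = soundSpeed / centerFrequency * 1e6
  )
}

#' MBTemplate: one microbubble point-spread template
#'
#' A small non-negative intensity patch with odd side length representing a
#' single microbubble's point-spread signature, peak-normalized to 1, plus
#' the sub-pixel offset of the true peak relative to the patch centre.
#'
#' @slot patch numeric matrix, odd side, values in `[0, 1]`.
#' @slot peakOffset numeric (row, col) sub-pixel peak offset in patch pixels.
#' @exportClass MBTemplate
setClass("MBTemplate",
  representation(patch = "matrix", peakOffset = "numeric")
)

setValidity("MBTemplate", function(object) {
  p <- object@patch
  msgs <- character()
  if (nrow(p) != ncol(p) || nrow(p) %% 2 == 0)
    msgs <- c(msgs, "patch must be square with odd side length")
  if (any(p < 0)) msgs <- c(msgs, "patch values must be non-negative")
  if (abs(max(p) - 1) > 1e-6 && max(p) > 1e-12)
    if (max(p) > 1 + 1e-9) msgs <- c(msgs, "patch maximum must not exceed 1")
  if (length(object@peakOffset) != 2)
    msgs <- c(msgs, "peakOffset must have length 2")
  ctr <- (nrow(p) - 1) / 2
  am <- which(p == max(p), arr.ind = TRUE)[1, ] - 1
  if (max(abs(am - (ctr + object@peakOffset))) > 1 + 1e-9)
    msgs <- c(msgs, "patch argmax must lie within 1 pixel of centre + peakOffset")
  if (length(msgs)) msgs else TRUE
})

#' TemplateBank: a collection of microbubble templates
#'
#' Stores templates together with the brightness statistics of the source
#' patches: the mean (`muImax`) and population standard deviation
#' (`sigmaImax`) of the patch maxima *before* per-patch peak normalization.
#' Simulated bubble brightness is drawn from N(muImax, sigmaImax).
#'
#' @slot templates list of [MBTemplate-class].
#' @slot muImax mean of source patch maxima (intensity units).
#' @slot sigmaImax population SD of source patch maxima.
#' @slot source one of "gaussian", "extracted", "lsgan".
#' @exportClass TemplateBank
setClass("TemplateBank",
  representation(templates = "list", muImax = "numeric",
                 sigmaImax = "numeric", source = "character")
)

setValidity("TemplateBank", function(object) {
  msgs <- character()
  if (length(object@templates) == 0) msgs <- c(msgs, "bank must be non-empty")
  if (object@sigmaImax < 0) msgs <- c(msgs, "sigmaImax must be >= 0")
  if (!object@source %in% c("gaussian", "extracted", "lsgan"))
    msgs <- c(msgs, "source must be gaussian, extracted or lsgan")
  sides <- vapply(object@templates, function(t) nrow(t@patch), integer(1))
  if (length(unique(sides)) > 1)
    msgs <- c(msgs, "all templates must share one side length")
  if (length(msgs)) msgs else TRUE
})

#' FrameStack: a T x H x W image stack with grid metadata
#'
#' @slot data numeric array, dimensions (frames, rows, cols), finite and
#'   non-negative (negative values may transiently appear only in complex
#'   intermediate stages; validity enforces >= 0).
#' @slot config the [ImagingConfig-class] the stack lives on.
#' @slot stage one of "fine", "input", "preprocessed", "noise".
#' @exportClass FrameStack
setClass("FrameStack",
  representation(data = "array", config = "ImagingConfig", stage = "character")
)

setValidity("FrameStack", function(object) {
  msgs <- character()
  if (length(dim(object@data)) != 3)
    msgs <- c(msgs, "data must be a 3-D array (frames, rows, cols)")
  if (!all(is.finite(object@data))) msgs <- c(msgs, "data must be finite")
  if (any(object@data < 0)) msgs <- c(msgs, "data must be non-negative")
  if (!object@stage %in% c("fine", "input", "preprocessed", "noise"))
    msgs <- c(msgs, "unknown stage tag")
  if (length(msgs)) msgs else TRUE
})

#' Construct a FrameStack
#'
#' @param data numeric 3-D array (frames, rows, cols).
#' @param config an [ImagingConfig-class].
#' @param stage grid stage tag ("fine", "input", "preprocessed", "noise").
#' @return a [FrameStack-class].
#' @export
frameStack <- function(data, config, stage = "input") {
  new("FrameStack", data = data, config = config, stage = stage)
}

#' NoiseModel: per-pixel Rician noise scale
#'
#' @slot sigmaMap H x W matrix of per-pixel noise SDs (intensity units).
#' @slot nSamples number of noise-only frames used for estimation.
#' @exportClass NoiseModel
setClass("NoiseModel",
  representation(sigmaMap = "matrix", nSamples = "integer")
)

setValidity("NoiseModel", function(object) {
  if (any(object@sigmaMap < 0)) "sigmaMap must be non-negative" else TRUE
})

#' Construct a spatially constant noise model
#'
#' Synthetic-data convention when no noise-only recording is available: a
#' constant noise SD, by default expressed as a fraction of the template
#' bank's mean brightness.
#'
#' @param sigma scalar noise SD (intensity units).
#' @param dim integer (rows, cols) of the target frame grid.
#' @return a [NoiseModel-class].
#' @export
noiseModel <- function(sigma, dim) {
  new("NoiseModel", sigmaMap = matrix(sigma, dim[1], dim[2]), nSamples = 0L)
}

#' GanModels: least-squares GAN generator/discriminator pair
#'
#' @slot generator list of generator parameters.
#' @slot discriminator list of discriminator parameters.
#' @slot latentDim latent vector length.
#' @slot side template side length produced by the generator.
#' @slot trainingLog data.frame of per-epoch discriminator/generator losses.
#' @slot muImax,sigmaImax brightness statistics copied from the training bank.
#' @exportClass GanModels
setClass("GanModels",
  representation(generator = "list", discriminator = "list",
                 latentDim = "integer", side = "integer",
                 trainingLog = "data.frame",
                 muImax = "numeric", sigmaImax = "numeric")
)

#' DecodeModel: trained context-aware localization network
#'
#' @slot params list of network parameters (frame-analysis U-Net, temporal
#'   context U-Net, output head).
#' @slot arch list of architecture hyperparameters (base filters, shared
#'   stem flag, input channels).
#' @slot trainLog data.frame of per-epoch training losses.
#' @exportClass DecodeModel
setClass("DecodeModel",
  representation(params = "list", arch = "list", trainLog = "data.frame")
)

# ---- accessors ----

#' @describeIn imagingConfig derived acoustic wavelength in micrometres.
#' @param cfg an ImagingConfig.
#' @export
wavelengthUm <- function(cfg) cfg@wavelengthUm

#' Field-of-view area in squared wavelengths
#' @param cfg an [ImagingConfig-class].
#' @return scalar FOV area in lambda^2 units.
#' @export
fovAreaLambda2 <- function(cfg) {
  prod(cfg@fovFine * cfg@finePixelUm / cfg@wavelengthUm)
}

#' @rdname accessors
#' @name accessors
#' @title Accessors for pipeline containers
#' @param x a pipeline object.
#' @param i template index.
#' @return the requested component.
NULL

#' @rdname accessors
#' @export
stackData <- function(x) x@data

#' @rdname accessors
#' @export
stackConfig <- function(x) x@config

#' @rdname accessors
#' @export
nTemplates <- function(x) length(x@templates)

#' @rdname accessors
#' @export
getTemplate <- function(x, i) x@templates[[i]]

#' @rdname accessors
#' @export
templatePatch <- function(x) x@patch

#' @rdname accessors
#' @export
bankStats <- function(x) c(muImax = x@muImax, sigmaImax = x@sigmaImax)

#' @rdname accessors
#' @export
sigmaMap <- function(x) x@sigmaMap

setMethod("show", "ImagingConfig", function(object) {
  cat(sprintf(
    "ImagingConfig: %.0f m/s, %.3f MHz (lambda %.3f um), %.0f Hz\n",
    object@soundSpeed, object@centerFrequency / 1e6, object@wavelengthUm,
    object@frameRate
  ))
  cat(sprintf(
    "  fine grid %d x %d at %.2f um, downsample x%d (input pixel %.2f um)\n",
    object@fovFine[1], object@fovFine[2], object@finePixelUm,
    object@downsample, object@finePixelUm * object@downsample
  ))
})

setMethod("show", "TemplateBank", function(object) {
  side <- nrow(object@templates[[1]]@patch)
  cat(sprintf(
    "TemplateBank: %d %s templates (%d x %d), muImax %.3f, sigmaImax %.3f\n",
    length(object@templates), object@source, side, side,
    object@muImax, object@sigmaImax
  ))
})

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("FrameStack [%s]: %d frames of %d x %d, range [%.3g, %.3g]\n",
              object@stage, d[1], d[2], d[3],
              min(object@data), max(object@data)))
})

setMethod("show", "NoiseModel", function(object) {
  cat(sprintf("NoiseModel: %d x %d sigma map, median sigma %.4g (N = %d)\n",
              nrow(object@sigmaMap), ncol(object@sigmaMap),
              stats::median(object@sigmaMap), object@nSamples))
})

setMethod("show", "DecodeModel", function(object) {
  np <- length(unlist(object@params, use.names = FALSE))
  cat(sprintf(
    "DecodeModel: base filters %d, %s frame stems, %.2fM parameters\n",
    object@arch$baseFilters,
    if (isTRUE(object@arch$sharedStem)) "shared" else "separate", np / 1e6
  ))
})

setMethod("show", "GanModels", function(object) {
  cat(sprintf("GanModels: latent dim %d -> %d x %d templates, %d epochs logged\n",
              object@latentDim, object@side, object@side,
              nrow(object@trainingLog)))
})
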