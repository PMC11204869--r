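#' @useDynLib plantsr, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' RasterImage: an in-memory 8-bit or unit-float raster
#'
#' The carrier for low-resolution inputs, high-resolution references and
#' super-resolved outputs. Pixels are stored as an `height x width x channels`
#' numeric array in row/column (top-left origin, 0-based coordinates at the
#' API surface) order. Two value ranges are supported: `"uint8"` (integers in
#' \[0, 255\]) and `"unit"` (floats in \[0, 1\]).
#'
#' @slot pixels numeric array of dimension `c(height, width, channels)`.
#' @slot range `"uint8"` or `"unit"`.
#' @exportClass RasterImage
setClass("RasterImage",
  representation(pixels = "array", range = "character"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3L)
      return("pixels must be a 3-d array (height x width x channels)")
    if (d[1] < 1L || d[2] < 1L)
      return("height and width must be >= 1")
    if (!d[3] %in% c(1L, 3L))
      return("channels must be 1 or 3")
    if (!object@range %in% c("uint8", "unit"))
      return("range must be 'uint8' or 'unit'")
    px <- object@pixels
    if (anyNA(px)) return("pixels contain NA")
    if (object@range == "uint8") {
      if (min(px) < 0 || max(px) > 255) return("uint8 pixels outside [0,255]")
      if (any(px != round(px))) return("uint8 pixels must be integers")
    } else {
      if (min(px) < 0 || max(px) > 1) return("unit pixels outside [0,1]")
    }
    TRUE
  }
)

#' DatasetManifest: a train/test listing of high-resolution images
#'
#' @slot entries data.frame with columns `path`, `split` (`"train"`/`"test"`)
#'   and `category` (optional label, `NA` allowed).
#' @slot root the dataset root directory.
#' @exportClass DatasetManifest
setClass("DatasetManifest",
  representation(entries = "data.frame", root = "character"),
  validity = function(object) {
    e <- object@entries
    need <- c("path", "split", "category")
    if (!all(need %in% names(e)))
      return("entries must have columns path, split, category")
    if (!all(e$split %in% c("train", "test")))
      return("split must be 'train' or 'test'")
    if (anyDuplicated(e$path)) return("splits must be disjoint (duplicate path)")
    TRUE
  }
)

#' DegradationConfig: the bicubic HR -> LR operator
#'
#' @slot scale integer downscaling factor (2, 3 or 4).
#' @slot antialias widen the kernel by the zoom factor when downsampling
#'   (the Matlab `imresize` convention; default `TRUE`).
#' @slot a sharpness parameter of the Keys cubic kernel (default -0.5).
#' @exportClass DegradationConfig
setClass("DegradationConfig",
  representation(scale = "integer", antialias = "logical", a = "numeric"),
  prototype(scale = 2L, antialias = TRUE, a = -0.5),
  validity = function(object) {
    if (object@scale < 1L) return("scale must be >= 1")
    TRUE
  }
)

#' MetricConfig: dynamic range and SSIM constants
#'
#' `c1` and `c2` are always `(0.01 * maxVal)^2` and `(0.03 * maxVal)^2`; they
#' are derived, not free.
#'
#' @slot maxVal dynamic range L (255 for 8-bit images).
#' @slot ssimMode `"windowed"` (11x11 Gaussian local statistics, the field
#'   standard) or `"global"` (one set of statistics for the whole image).
#' @slot windowSize odd window side in px for windowed mode.
#' @slot windowSigma Gaussian sigma in px for windowed mode.
#' @exportClass MetricConfig
setClass("MetricConfig",
  representation(maxVal = "numeric", ssimMode = "character",
                 windowSize = "integer", windowSigma = "numeric"),
  prototype(maxVal = 255, ssimMode = "windowed",
            windowSize = 11L, windowSigma = 1.5),
  validity = function(object) {
    if (object@maxVal <= 0) return("maxVal must be > 0")
    if (!object@ssimMode %in% c("windowed", "global"))
      return("ssimMode must be 'windowed' or 'global'")
    if (object@windowSize < 1L || object@windowSize %% 2L == 0L)
      return("windowSize must be odd and >= 1")
    TRUE
  }
)

#' PlantSRConfig: hyper-parameters that fully determine a PlantSR network
#'
#' @slot scale upscaling factor s (2, 3 or 4).
#' @slot channels feature-map width C.
#' @slot m residual groups in the second shallow-feature stage (may be 0).
#' @slot n residual groups in the deep-feature stage (>= 1).
#' @slot rsebPerGroup residual SE-attention blocks per group (4 by default).
#' @slot seReduction SE bottleneck divisor r; must divide `channels`.
#' @exportClass PlantSRConfig
setClass("PlantSRConfig",
  representation(scale = "integer", channels = "integer", m = "integer",
                 n = "integer", rsebPerGroup = "integer",
                 seReduction = "integer"),
  prototype(scale = 2L, channels = 64L, m = 2L, n = 4L,
            rsebPerGroup = 4L, seReduction = 16L),
  validity = function(object) {
    if (!object@scale %in% 2:4) return("scale must be 2, 3 or 4")
    if (object@m < 0L) return("m must be >= 0")
    if (object@n < 1L) return("n must be >= 1")
    if (object@rsebPerGroup < 1L) return("rsebPerGroup must be >= 1")
    if (object@channels < object@seReduction ||
        object@channels %% object@seReduction != 0L)
      return("channels must be a positive multiple of seReduction")
    TRUE
  }
)

#' SRModel: a super-resolution network with its weights
#'
#' A lightweight container: `name` selects the architecture family
#' (`"plantsr"`, `"srcnn"`, `"vdsr"`, `"edsr"`), `scale` the upscaling factor,
#' `config` the architecture hyper-parameters, and `params` the nested list of
#' numeric weight arrays. SRCNN and VDSR are pre-upsampling networks (they
#' refine a bicubic-upscaled input); EDSR and PlantSR are post-upsampling.
#'
#' @slot name architecture family.
#' @slot scale integer upscaling factor.
#' @slot config named list of architecture hyper-parameters.
#' @slot params nested named list of numeric parameter arrays.
#' @slot provenance character; path of the parent checkpoint for fine-tuned
#'   models, `NA` otherwise.
#' @exportClass SRModel
setClass("SRModel",
  representation(name = "character", scale = "integer", config = "list",
                 params = "list", provenance = "character"),
  prototype(provenance = NA_character_),
  validity = function(object) {
    if (!object@name %in% c("plantsr", "srcnn", "vdsr", "edsr"))
      return("unknown architecture name")
    if (object@scale < 1L) return("scale must be >= 1")
    TRUE
  }
)

#' TrainConfig: patch-based training settings
#'
#' Defaults follow the published protocol: 32 patches per batch, 64 px
#' high-resolution patches (63 px for scale 3 so the patch divides by the
#' scale), Adam at an initial learning rate of 1e-4, horizontal-flip
#' augmentation.
#'
#' @slot batchSize patches per optimization step.
#' @slot patchSize high-resolution patch side in px; must divide by the scale.
#' @slot lr0 initial Adam step size.
#' @slot beta1,beta2,eps Adam moment decays and stabilizer.
#' @slot batchesPerEpoch optimization steps per epoch.
#' @slot epochs number of epochs.
#' @slot seed RNG seed driving patch sampling and augmentation.
#' @slot hflip apply horizontal flips with probability 1/2.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(batchSize = "integer", patchSize = "integer", lr0 = "numeric",
                 beta1 = "numeric", beta2 = "numeric", eps = "numeric",
                 batchesPerEpoch = "integer", epochs = "integer",
                 seed = "integer", hflip = "logical"),
  prototype(batchSize = 32L, patchSize = 64L, lr0 = 1e-4, beta1 = 0.9,
            beta2 = 0.999, eps = 1e-8, batchesPerEpoch = 100L, epochs = 1L,
            seed = 0L, hflip = TRUE),
  validity = function(object) {
    if (object@batchSize < 1L) return("batchSize must be >= 1")
    if (object@lr0 < 0) return("lr0 must be >= 0")
    if (object@patchSize < 1L) return("patchSize must be >= 1")
    TRUE
  }
)

#' SynthSpec: parameters of the synthetic plant-texture generator
#'
#' @slot height,width image size in px (>= 16).
#' @slot seed RNG seed; the same spec always yields a bit-identical image.
#' @slot nFrequencies number of random sinusoidal gratings.
#' @slot edgeDensity approximate fraction of pixels on sharp ridge structures.
#' @slot palette `"green"` (default) or `"brown"` base tones.
#' @exportClass SynthSpec
setClass("SynthSpec",
  representation(height = "integer", width = "integer", seed = "integer",
                 nFrequencies = "integer", edgeDensity = "numeric",
                 palette = "character"),
  prototype(height = 96L, width = 96L, seed = 0L, nFrequencies = 24L,
            edgeDensity = 0.08, palette = "green"),
  validity = function(object) {
    if (object@height < 16L || object@width < 16L)
      return("height and width must be >= 16")
    if (object@nFrequencies < 1L) return("nFrequencies must be >= 1")
    if (object@edgeDensity < 0 || object@edgeDensity > 1)
      return("edgeDensity must lie in [0,1]")
    TRUE
  }
)
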