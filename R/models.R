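#' PlantSR configuration with depth-scaled per-scale defaults
#'
#' The published parameter budget grows steeply with scale; the default
#' presets reproduce that growth by deepening the deep-feature stage
#' (`n = 4, 8, 12` residual groups for scales 2, 3, 4) at fixed width
#' `C = 64`, `m = 2` shallow groups and SE reduction 16.
#'
#' @param scale upscaling factor (2, 3 or 4).
#' @param channels feature-map width C.
#' @param m shallow-stage residual groups (0 degenerates the stage to the
#'   identity).
#' @param n deep-stage residual groups; default depends on `scale`.
#' @param rsebPerGroup residual SE-attention blocks per group.
#' @param seReduction SE bottleneck divisor r.
#' @return A [PlantSRConfig-class].
#' @export
PlantSRConfig <- function(scale = 2L, channels = 64L, m = 2L, n = NULL,
                          rsebPerGroup = 4L, seReduction = 16L) {
  scale <- as.integer(scale)
  if (is.null(n)) n <- c(`2` = 4L, `3` = 8L, `4` = 12L)[as.character(scale)]
  new("PlantSRConfig", scale = scale, channels = as.integer(channels),
      m = as.integer(m), n = as.integer(n),
      rsebPerGroup = as.integer(rsebPerGroup),
      seReduction = as.integer(seReduction))
}

#' Build one Residual SE-attention Block (RSEB)
#'
#' The block computes `x + SE(conv(relu(conv(x))))`: two 3x3 convolutions
#' with a ReLU between them, a squeeze-and-excitation gate, and a residual
#' connection from the block input. With all convolution weights and biases
#' zero the block is exactly the identity.
#'
#' @param C channel width.
#' @param r SE bottleneck divisor; must divide `C`.
#' @return A named parameter list (`conv1`, `conv2`, `se`), usable with
#'   [countParameters()].
#' @export
buildRSEB <- function(C, r) {
  if (C %% r != 0L || C < r) stop("C must be a positive multiple of r")
  list(conv1 = convParam(C, C, 3L, scale = 0.1),
       conv2 = convParam(C, C, 3L, scale = 0.1),
       se = seParam(C, r))
}

# the trailing conv starts at zero so every group begins as the identity
# and the group skip carries the signal; its weights move off zero during
# training (the standard stabilization for deep residual SR stacks)
buildResidualGroup <- function(C, r, nBlocks) {
  list(blocks = lapply(seq_len(nBlocks), function(i) buildRSEB(C, r)),
       gconv = convParam(C, C, 3L, init = "zero"))
}

#' Build a PlantSR network
#'
#' Three modules: shallow feature extraction (one 3x3 conv producing `F0`,
#' then `m` residual groups producing `F1`), deep feature extraction (`n`
#' residual groups producing `F_DF`), and reconstruction
#' `H_UP(F0 + F1 + F_DF)` — a conv expanding to `C * s^2` channels, a pixel
#' shuffle by `s`, and a conv back to RGB. Each residual group is
#' `rsebPerGroup` RSEBs followed by a 3x3 conv, plus a skip from the group
#' input, so a zero-weight group is exactly the identity.
#'
#' @param cfg a [PlantSRConfig-class].
#' @param seed RNG seed for weight initialization.
#' @return An [SRModel-class].
#' @export
buildPlantSR <- function(cfg = PlantSRConfig(), seed = 1L) {
  validObject(cfg)
  C <- cfg@channels; s <- cfg@scale
  params <- withSeed(seed, {
    groups <- lapply(seq_len(cfg@m + cfg@n), function(i)
      buildResidualGroup(C, cfg@seReduction, cfg@rsebPerGroup))
    list(conv0 = convParam(3L, C, 3L),
         groups = groups,
         head1 = convParam(C, C * s * s, 3L, scale = 0.1),
         head2 = convParam(C, 3L, 3L, scale = 0.1))
  })
  new("SRModel", name = "plantsr", scale = s,
      config = list(scale = s, channels = C, m = cfg@m, n = cfg@n,
                    rsebPerGroup = cfg@rsebPerGroup,
                    seReduction = cfg@seReduction),
      params = params)
}

#' Build the SRCNN reference network
#'
#' A pre-upsampling three-layer net on RGB: 9x9 conv 3->64 + ReLU, 5x5 conv
#' 64->32 + ReLU, 5x5 conv 32->3, applied to the bicubic-upscaled input.
#' 69,251 parameters (0.069 M).
#'
#' @param scale upscaling factor used for the bicubic pre-upsampling step.
#' @param seed RNG seed for weight initialization.
#' @return An [SRModel-class].
#' @export
buildSRCNN <- function(scale = 2L, seed = 1L) {
  params <- withSeed(seed, list(
    conv1 = convParam(3L, 64L, 9L),
    conv2 = convParam(64L, 32L, 5L),
    conv3 = convParam(32L, 3L, 5L)))
  new("SRModel", name = "srcnn", scale = as.integer(scale),
      config = list(scale = as.integer(scale)), params = params)
}

#' Build the VDSR reference network
#'
#' A pre-upsampling 20-layer net on RGB: 3x3 convolutions at 64 channels
#' (first 3->64, last 64->3) with ReLU between, all bias-free, and a global
#' residual connection from the bicubic-upscaled input to the output.
#' 667,008 parameters (0.667 M); with zero weights the net is the identity.
#'
#' @inheritParams buildSRCNN
#' @return An [SRModel-class].
#' @export
buildVDSR <- function(scale = 2L, seed = 1L) {
  params <- withSeed(seed, {
    convs <- c(list(convParam(3L, 64L, 3L, bias = FALSE)),
               lapply(1:18, function(i) convParam(64L, 64L, 3L, bias = FALSE)),
               list(convParam(64L, 3L, 3L, bias = FALSE)))
    list(convs = convs)
  })
  new("SRModel", name = "vdsr", scale = as.integer(scale),
      config = list(scale = as.integer(scale)), params = params)
}

#' Build the EDSR baseline network
#'
#' The post-upsampling baseline configuration: a 3x3 head conv 3->64,
#' 16 residual blocks (conv-ReLU-conv at 64 channels, unscaled residual), a
#' 3x3 conv with a global skip to the head output, a pixel-shuffle upsampler
#' (one x2 stage for scale 2, one x3 stage for scale 3, two x2 stages for
#' scale 4) and a final conv 64->3. Parameter counts: 1,369,859 (x2),
#' 1,554,499 (x3), 1,517,571 (x4).
#'
#' @param scale 2, 3 or 4.
#' @param seed RNG seed for weight initialization.
#' @return An [SRModel-class].
#' @export
buildEDSR <- function(scale = 2L, seed = 1L) {
  scale <- as.integer(scale)
  if (!scale %in% 2:4) stop("unsupported scale for EDSR: ", scale)
  stages <- if (scale == 4L) c(2L, 2L) else scale
  params <- withSeed(seed, list(
    head = convParam(3L, 64L, 3L),
    blocks = lapply(1:16, function(i)
      list(conv1 = convParam(64L, 64L, 3L, scale = 0.1),
           conv2 = convParam(64L, 64L, 3L, scale = 0.1))),
    convB = convParam(64L, 64L, 3L),
    up = lapply(stages, function(st) convParam(64L, 64L * st * st, 3L)),
    convOut = convParam(64L, 3L, 3L)))
  new("SRModel", name = "edsr", scale = scale,
      config = list(scale = scale, stages = stages), params = params)
}

#' Count trainable parameters
#'
#' Total number of trainable scalars in a network or parameter block.
#' Bias-free convolutions contribute no bias terms.
#'
#' @param object an [SRModel-class] or a nested parameter list (e.g. from
#'   [buildRSEB()]).
#' @return integer count.
#' @export
setGeneric("countParameters", function(object) standardGeneric("countParameters"))

#' @rdname countParameters
#' @export
setMethod("countParameters", "SRModel", function(object)
  as.integer(paramLeafCount(object@params)))

#' @rdname countParameters
#' @export
setMethod("countParameters", "list", function(object)
  as.integer(paramLeafCount(object)))

setMethod("show", "SRModel", function(object) {
  cat(sprintf("SRModel '%s' (x%d), %s parameters\n", object@name,
              object@scale, format(countParameters(object), big.mark = ",")))
  if (!is.na(object@provenance))
    cat("  fine-tuned from:", object@provenance, "\n")
})

#' @describeIn countParameters accessor for the model's upscaling factor
#' @export
modelScale <- function(object) object@scale

#' Save a model checkpoint
#'
#' Writes the weights in R's native serialization (`.ckpt`) plus a JSON
#' sidecar (`<path>.json`) carrying the architecture configuration and
#' provenance, so a checkpoint is self-describing.
#'
#' @param model an [SRModel-class].
#' @param path output path (conventionally `*.ckpt`).
#' @return `path`, invisibly.
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(name = model@name, scale = model@scale, config = model@config,
               params = model@params, provenance = model@provenance), path)
  jsonlite::write_json(
    list(name = model@name, scale = model@scale, config = model@config,
         provenance = model@provenance,
         parameters = countParameters(model)),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Load a model checkpoint written by [saveCheckpoint()]
#'
#' @param path checkpoint path.
#' @return An [SRModel-class].
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  x <- readRDS(path)
  new("SRModel", name = x$name, scale = x$scale, config = x$config,
      params = x$params,
      provenance = if (is.null(x$provenance)) NA_character_ else x$provenance)
}
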