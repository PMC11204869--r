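#' Degradation operator configuration
#'
#' @param scale integer downscaling factor.
#' @param antialias widen the kernel by the zoom factor when downsampling
#'   (Matlab `imresize` convention); irrelevant when upsampling.
#' @param a Keys kernel sharpness (default -0.5, the de-facto standard for
#'   super-resolution benchmarks).
#' @return A [DegradationConfig-class].
#' @export
DegradationConfig <- function(scale = 2L, antialias = TRUE, a = -0.5) {
  new("DegradationConfig", scale = as.integer(scale),
      antialias = antialias, a = a)
}

#' Keys cubic kernel
#'
#' The piecewise-cubic interpolation kernel
#' \deqn{w(t) = (a+2)|t|^3 - (a+3)|t|^2 + 1, \quad |t| \le 1}
#' \deqn{w(t) = a|t|^3 - 5a|t|^2 + 8a|t| - 4a, \quad 1 < |t| < 2}
#' and 0 elsewhere. It is even, equals 1 at the origin and 0 at the integer
#' knots, and its translates sum to 1 for `a = -0.5`.
#'
#' @param t offset from the sample position, in output-grid units (vectorized).
#' @param a sharpness parameter.
#' @return kernel weights, same length as `t`.
#' @export
cubicWeight <- function(t, a = -0.5) {
  at <- abs(t)
  w <- numeric(length(at))
  i1 <- at <= 1
  w[i1] <- (a + 2) * at[i1]^3 - (a + 3) * at[i1]^2 + 1
  i2 <- at > 1 & at < 2
  w[i2] <- a * at[i2]^3 - 5 * a * at[i2]^2 + 8 * a * at[i2] - 4 * a
  w
}

# Dense (nOut x nIn) resampling matrix along one axis.
# Center-aligned mapping: output pixel i (1-based) samples input coordinate
# u = (i - 0.5) / zoom + 0.5. When downsampling with antialias, the kernel is
# stretched by 1/zoom and weights rescaled accordingly. Out-of-range taps are
# clamped to the edge (replication) by folding their weights onto the border
# sample. Weights are normalized to sum to one per output pixel.
resampleMatrix <- function(nIn, nOut, a = -0.5, antialias = TRUE) {
  zoom <- nOut / nIn
  ks <- if (antialias && zoom < 1) zoom else 1
  support <- 2 / ks
  M <- matrix(0, nOut, nIn)
  for (i in seq_len(nOut)) {
    u <- (i - 0.5) / zoom + 0.5
    lo <- floor(u - support)
    taps <- lo:(lo + ceiling(2 * support) + 1)
    w <- ks * cubicWeight(ks * (u - taps), a)
    keep <- w != 0
    taps <- taps[keep]; w <- w[keep]
    w <- w / sum(w)
    taps <- pmin(pmax(taps, 1), nIn)       # edge replication
    for (k in seq_along(taps)) M[i, taps[k]] <- M[i, taps[k]] + w[k]
  }
  M
}

#' Separable bicubic resampling
#'
#' Resamples an image to `outH x outW` with the Keys cubic kernel,
#' center-aligned coordinates, edge replication at the borders, and (for
#' downsampling) optional antialiasing by kernel dilation — the convention of
#' Matlab's `imresize`, which dominates the super-resolution literature.
#' The output is clamped to the valid range of the input representation
#' (uint8 outputs are additionally rounded half away from zero).
#'
#' @param img a `RasterImage`.
#' @param outH,outW output size in px (>= 1).
#' @param cfg a [DegradationConfig-class] supplying the kernel parameters.
#' @return `RasterImage` of size `outH x outW` in the same range as `img`.
#' @export
resizeBicubic <- function(img, outH, outW, cfg = DegradationConfig()) {
  if (outH < 1 || outW < 1) stop("output size must be >= 1 in both dims")
  px <- img@pixels
  d <- dim(px)
  Mr <- resampleMatrix(d[1L], outH, cfg@a, cfg@antialias)
  Mc <- resampleMatrix(d[2L], outW, cfg@a, cfg@antialias)
  out <- array(0, c(outH, outW, d[3L]))
  for (ch in seq_len(d[3L]))
    out[, , ch] <- Mr %*% px[, , ch] %*% t(Mc)
  if (img@range == "uint8") {
    out <- sign(out) * floor(abs(out) + 0.5)
    out <- pmin(pmax(out, 0), 255)
  } else {
    out <- pmin(pmax(out, 0), 1)
  }
  RasterImage(out, img@range)
}

#' Synthesize an LR/HR training pair from a high-resolution image
#'
#' Crops the image at the top-left corner so both dimensions are multiples of
#' the scale, then bicubic-downsamples the crop by the scale factor. This is
#' the standard degradation pipeline for super-resolution benchmarks.
#'
#' @param hr a `RasterImage` of at least `scale` px in each dimension.
#' @param cfg a [DegradationConfig-class].
#' @return A list with elements `lr` and `hr` (the cropped reference).
#' @export
#' @examples
#' hr <- RasterImage(array(round(runif(65 * 65 * 3) * 255), c(65, 65, 3)))
#' pair <- makeLRHRPair(hr, DegradationConfig(scale = 2))
#' dim(imgPixels(pair$lr))   # 32 32 3
makeLRHRPair <- function(hr, cfg = DegradationConfig()) {
  s <- cfg@scale
  d <- dim(hr@pixels)
  if (d[1L] < s || d[2L] < s)
    stop(sprintf("image %dx%d smaller than scale %d", d[1L], d[2L], s))
  ch <- (d[1L] %/% s) * s
  cw <- (d[2L] %/% s) * s
  hrC <- RasterImage(hr@pixels[seq_len(ch), seq_len(cw), , drop = FALSE],
                     hr@range)
  lr <- resizeBicubic(hrC, ch %/% s, cw %/% s, cfg)
  list(lr = lr, hr = hrC)
}
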