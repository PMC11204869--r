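#' Construct a RasterImage
#'
#' @param pixels numeric array `height x width x channels` (a matrix is
#'   promoted to a single-channel array).
#' @param range `"uint8"` or `"unit"`.
#' @return A [RasterImage-class] object.
#' @export
#' @examples
#' img <- RasterImage(array(0:3, c(2, 2, 1)), "uint8")
#' imgHeight(img)
RasterImage <- function(pixels, range = c("uint8", "unit")) {
  range <- match.arg(range)
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  storage.mode(pixels) <- "double"
  new("RasterImage", pixels = pixels, range = range)
}

#' @describeIn RasterImage pixel array accessor
#' @param img a `RasterImage`
#' @export
imgPixels <- function(img) img@pixels

#' @describeIn RasterImage value range accessor (`"uint8"` or `"unit"`)
#' @export
imgRange <- function(img) img@range

#' @describeIn RasterImage image height in px
#' @export
imgHeight <- function(img) dim(img@pixels)[1L]

#' @describeIn RasterImage image width in px
#' @export
imgWidth <- function(img) dim(img@pixels)[2L]

#' @describeIn RasterImage number of channels
#' @export
imgChannels <- function(img) dim(img@pixels)[3L]

setMethod("show", "RasterImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("RasterImage %dx%d, %d channel(s), range %s [%.4g, %.4g]\n",
              d[1], d[2], d[3], object@range,
              min(object@pixels), max(object@pixels)))
})

#' Read a PNG or JPEG file as an 8-bit RGB RasterImage
#'
#' Grayscale sources are promoted to three identical channels; an alpha
#' channel is dropped. The file type is detected from the magic bytes, so a
#' mislabelled extension still decodes.
#'
#' @param path path to a PNG or JPEG file.
#' @return `RasterImage` in `"uint8"` range with 3 channels.
#' @export
readRaster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  magic <- readBin(path, "raw", n = 3L)
  px <- if (length(magic) >= 3L && identical(magic[1:3], as.raw(c(0x89, 0x50, 0x4e)))) {
    png::readPNG(path)
  } else if (length(magic) >= 2L && identical(magic[1:2], as.raw(c(0xff, 0xd8)))) {
    jpeg::readJPEG(path)
  } else {
    stop("cannot decode '", path, "': not a PNG or JPEG file")
  }
  if (length(dim(px)) == 2L) px <- array(px, c(dim(px), 1L))
  nc <- dim(px)[3L]
  if (nc == 2L) px <- px[, , 1L, drop = FALSE]          # gray + alpha
  if (nc == 4L) px <- px[, , 1:3, drop = FALSE]          # drop alpha
  if (dim(px)[3L] == 1L) px <- px[, , c(1L, 1L, 1L), drop = FALSE]
  # codecs return [0,1] floats backed by 8-bit samples: recover exact integers
  RasterImage(round(px * 255), "uint8")
}

#' Write a RasterImage as a PNG file
#'
#' PNG is lossless for 8-bit data, so `writeRaster` then [readRaster] is the
#' identity on uint8 images.
#'
#' @param img a `RasterImage` (converted to uint8 if needed).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRaster <- function(img, path) {
  img <- toUint8(img)
  png::writePNG(img@pixels / 255, target = path)
  invisible(path)
}

#' Convert a uint8 image to unit-float range
#'
#' Divides by 255 exactly. Applying it to an already-float image is a no-op
#' with a warning.
#'
#' @param img a `RasterImage`.
#' @return `RasterImage` in `"unit"` range.
#' @export
toUnitFloat <- function(img) {
  if (img@range == "unit") {
    warning("image already in unit-float range; no-op")
    return(img)
  }
  RasterImage(img@pixels / 255, "unit")
}

#' Convert a unit-float image to uint8 range
#'
#' Multiplies by 255, rounds half away from zero, and clamps to \[0, 255\].
#' Under this rule `toUint8(toUnitFloat(x))` is the identity on all 256
#' uint8 values.
#'
#' @param img a `RasterImage`.
#' @return `RasterImage` in `"uint8"` range.
#' @export
toUint8 <- function(img) {
  if (img@range == "uint8") return(img)
  RasterImage(quantizeUnit(img@pixels), "uint8")
}

# unit-float array -> uint8 values: round half away from zero, clamp [0,255]
quantizeUnit <- function(px) {
  v <- px * 255
  v <- sign(v) * floor(abs(v) + 0.5)
  pmin(pmax(v, 0), 255)
}

#' Extract a square patch from an image
#'
#' Coordinates are 0-based with the origin at the top-left pixel. The patch
#' must lie fully inside the image: there is no implicit padding.
#'
#' @param img a `RasterImage`.
#' @param top,left 0-based corner of the patch.
#' @param size patch side in px.
#' @return `RasterImage` of dimension `size x size` (an independent copy).
#' @export
extractPatch <- function(img, top, left, size) {
  d <- dim(img@pixels)
  if (top < 0 || left < 0 || size < 1 ||
      top + size > d[1L] || left + size > d[2L])
    stop(sprintf("patch [%d+%d, %d+%d] out of bounds for %dx%d image",
                 top, size, left, size, d[1L], d[2L]))
  RasterImage(img@pixels[(top + 1):(top + size),
                         (left + 1):(left + size), , drop = FALSE],
              img@range)
}
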