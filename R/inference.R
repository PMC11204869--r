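#' Plan a tiling of the LR frame for memory-bounded inference
#'
#' Tiles of side `tile` px with `overlap` px of overlap cover the image;
#' the final tile in each dimension is shifted left/up so the cover is exact
#' for any image size. Overlapping output regions are averaged at assembly.
#'
#' @param height,width LR image size in px.
#' @param tile tile side in px (defaults to 128; images smaller than the
#'   tile are processed in one piece).
#' @param overlap overlap between neighbouring tiles in px (`>= 0`, `< tile`).
#' @return list with `tile`, `overlap` and data.frame `grid` of tile corners
#'   (`top`, `left`, 0-based, LR frame) and sides (`h`, `w`).
#' @export
makeTilingPlan <- function(height, width, tile = 128L, overlap = 16L) {
  if (overlap < 0L) stop("overlap must be >= 0")
  if (tile <= overlap) stop("tile must be larger than the overlap")
  starts <- function(n) {
    if (n <= tile) return(0L)
    s <- seq(0L, n - tile, by = tile - overlap)
    if (s[length(s)] != n - tile) s <- c(s, n - tile)
    as.integer(s)
  }
  g <- expand.grid(top = starts(height), left = starts(width))
  g$h <- pmin(tile, height)
  g$w <- pmin(tile, width)
  list(tile = as.integer(tile), overlap = as.integer(overlap), grid = g)
}

#' Super-resolve a full image, tiling large inputs
#'
#' Tiles are processed independently and assembled at `scale` times the
#' input size; overlapping regions are averaged. Away from tile seams the
#' result is identical to a single whole-image forward pass (the networks
#' are translation-equivariant up to their receptive field at the seams).
#'
#' @param model an [SRModel-class].
#' @param img a `RasterImage` (RGB).
#' @param tile,overlap tiling parameters in the LR frame (see
#'   [makeTilingPlan()]); the default 128/16 keeps memory modest while the
#'   overlap exceeds the receptive-field growth of the default networks.
#' @return unit-float `RasterImage` of size `scale` times `img`.
#' @export
upscaleImage <- function(model, img, tile = 128L, overlap = 16L) {
  if (imgChannels(img) != 3L) stop("network input must be RGB")
  s <- model@scale
  H <- imgHeight(img); W <- imgWidth(img)
  plan <- makeTilingPlan(H, W, tile, overlap)
  if (nrow(plan$grid) == 1L) return(srForward(model, img))
  x <- toUnitFloatArray(img)
  acc <- array(0, c(H * s, W * s, 3L))
  wgt <- array(0, c(H * s, W * s, 1L))
  for (t in seq_len(nrow(plan$grid))) {
    g <- plan$grid[t, ]
    xt <- x[g$top + seq_len(g$h), g$left + seq_len(g$w), , drop = FALSE]
    yt <- netForward(model, xt)$out
    ri <- g$top * s + seq_len(g$h * s)
    ci <- g$left * s + seq_len(g$w * s)
    acc[ri, ci, ] <- acc[ri, ci, ] + yt[, , , 1L]
    wgt[ri, ci, 1L] <- wgt[ri, ci, 1L] + 1
  }
  out <- acc / as.vector(wgt)
  RasterImage(pmin(pmax(out, 0), 1), "unit")
}

#' Upscale every image in a folder
#'
#' The preprocessing entry point for downstream detection pipelines: each
#' decodable image in `inDir` is super-resolved and written to `outDir`
#' under the same basename (as PNG). Unreadable files are recorded in the
#' report and processing continues.
#'
#' @param model an [SRModel-class] or a checkpoint path.
#' @param inDir input directory.
#' @param outDir output directory (created if needed).
#' @param overwrite overwrite existing outputs; if `FALSE`, existing outputs
#'   are reported as `"skipped"`.
#' @param tile,overlap tiling parameters passed to [upscaleImage()].
#' @return data.frame report: `file`, `status` (`"ok"`, `"failed"`,
#'   `"skipped"`), `inHeight`, `inWidth`, `outHeight`, `outWidth`.
#' @export
upscaleFolder <- function(model, inDir, outDir, overwrite = FALSE,
                          tile = 128L, overlap = 16L) {
  if (is.character(model)) model <- loadCheckpoint(model)
  if (!dir.exists(inDir)) stop("input directory not found: ", inDir)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  files <- sort(list.files(inDir, pattern = "\\.(png|jpg|jpeg)$",
                           ignore.case = TRUE))
  if (length(files) == 0L) {
    warning("no images found in ", inDir)
    return(data.frame(file = character(0), status = character(0),
                      inHeight = integer(0), inWidth = integer(0),
                      outHeight = integer(0), outWidth = integer(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(files, function(f) {
    outPath <- file.path(outDir,
                         paste0(tools::file_path_sans_ext(f), ".png"))
    if (file.exists(outPath) && !overwrite)
      return(data.frame(file = f, status = "skipped", inHeight = NA,
                        inWidth = NA, outHeight = NA, outWidth = NA,
                        stringsAsFactors = FALSE))
    tryCatch({
      img <- readRaster(file.path(inDir, f))
      sr <- upscaleImage(model, img, tile, overlap)
      writeRaster(sr, outPath)
      data.frame(file = f, status = "ok",
                 inHeight = imgHeight(img), inWidth = imgWidth(img),
                 outHeight = imgHeight(sr), outWidth = imgWidth(sr),
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(file = f, status = "failed", inHeight = NA, inWidth = NA,
                 outHeight = NA, outWidth = NA, stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

#' Rescale a point-merging distance cutoff after upscaling
#'
#' Detection post-processing that merges nearby point predictions within a
#' radius (e.g. a k-d-tree neighbourhood query) must grow that radius with
#' the pixel density: distances in an image upscaled by `scale` are `scale`
#' times larger, so the cutoff is multiplied by the scale (doubled for a x2
#' pipeline).
#'
#' @param cutoff merge radius in px of the original frame (> 0).
#' @param scale upscaling factor (>= 1).
#' @return the cutoff in the upscaled frame, `cutoff * scale`.
#' @export
scaleDistanceCutoff <- function(cutoff, scale) {
  if (any(cutoff <= 0)) stop("cutoff must be > 0")
  if (any(scale < 1)) stop("scale must be >= 1")
  cutoff * scale
}
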