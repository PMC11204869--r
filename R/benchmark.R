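#' Evaluate a model (or the bicubic baseline) on a manifest split
#'
#' For each high-resolution image of the split: crop to a multiple of the
#' scale, bicubic-downsample, reconstruct, and score PSNR/SSIM against the
#' cropped reference. `model = "bicubic"` evaluates plain bicubic upscaling,
#' the classical baseline.
#'
#' @param model an [SRModel-class], a checkpoint path, or `"bicubic"`.
#' @param manifest a [DatasetManifest-class].
#' @param split `"test"` (default) or `"train"`.
#' @param degradation a [DegradationConfig-class] defining the LR synthesis.
#' @param metricCfg a [MetricConfig-class].
#' @return data.frame with one row per image (`imageId`, `psnr`, `ssim`)
#'   and a `summary` attribute holding the means.
#' @export
evaluateModel <- function(model, manifest, split = c("test", "train"),
                          degradation = DegradationConfig(),
                          metricCfg = MetricConfig()) {
  split <- match.arg(split)
  if (is.character(model) && !identical(model, "bicubic"))
    model <- loadCheckpoint(model)
  paths <- manifestPaths(manifest, split)
  rows <- lapply(seq_along(paths), function(i) {
    hr <- readRaster(paths[i])
    pair <- makeLRHRPair(hr, degradation)
    sr <- if (identical(model, "bicubic")) {
      resizeBicubic(pair$lr, imgHeight(pair$hr), imgWidth(pair$hr),
                    degradation)
    } else {
      toUint8(srForward(model, pair$lr))
    }
    data.frame(imageId = basename(paths[i]),
               psnr = psnr(sr, pair$hr, metricCfg),
               ssim = ssim(sr, pair$hr, metricCfg),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  attr(res, "summary") <- c(psnr = mean(res$psnr), ssim = mean(res$ssim))
  res
}

#' Benchmark several methods into a comparison-table report
#'
#' Evaluates each entry of `models` plus the bicubic baseline on the test
#' split and reports one row per method with mean PSNR, mean SSIM and
#' parameter count in millions — the layout of a standard super-resolution
#' comparison table.
#'
#' @param models named list of [SRModel-class] objects (names label the rows).
#' @param manifest a [DatasetManifest-class].
#' @param degradation a [DegradationConfig-class].
#' @param metricCfg a [MetricConfig-class].
#' @param file optional CSV path to write the report to.
#' @return data.frame with columns `method`, `scale`, `psnr`, `ssim`,
#'   `params_millions`.
#' @export
benchmarkReport <- function(models, manifest,
                            degradation = DegradationConfig(),
                            metricCfg = MetricConfig(), file = NULL) {
  bic <- attr(evaluateModel("bicubic", manifest, "test", degradation,
                            metricCfg), "summary")
  rows <- list(data.frame(
    method = "bicubic", scale = degradation@scale,
    psnr = bic[["psnr"]], ssim = bic[["ssim"]],
    params_millions = NA_real_, stringsAsFactors = FALSE))
  for (nm in names(models)) {
    ev <- evaluateModel(models[[nm]], manifest, "test", degradation,
                        metricCfg)
    s <- attr(ev, "summary")
    rows[[length(rows) + 1L]] <- data.frame(
      method = nm, scale = models[[nm]]@scale,
      psnr = s[["psnr"]], ssim = s[["ssim"]],
      params_millions = countParameters(models[[nm]]) / 1e6,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (!is.null(file)) utils::write.csv(res, file, row.names = FALSE)
  res
}
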