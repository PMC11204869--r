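#' Metric configuration
#'
#' `c1 = (0.01 * maxVal)^2` and `c2 = (0.03 * maxVal)^2` are derived from the
#' dynamic range and exposed through [metricC1()]/[metricC2()].
#'
#' @param maxVal dynamic range L (255 for 8-bit).
#' @param ssimMode `"windowed"` (default; 11x11 Gaussian window, sigma 1.5)
#'   or `"global"` (single whole-image statistics).
#' @param windowSize,windowSigma window parameters for windowed mode.
#' @return A [MetricConfig-class].
#' @export
MetricConfig <- function(maxVal = 255, ssimMode = c("windowed", "global"),
                         windowSize = 11L, windowSigma = 1.5) {
  ssimMode <- match.arg(ssimMode)
  new("MetricConfig", maxVal = maxVal, ssimMode = ssimMode,
      windowSize = as.integer(windowSize), windowSigma = windowSigma)
}

#' @describeIn MetricConfig the SSIM stabilizer `(0.01 L)^2`
#' @param cfg a `MetricConfig`
#' @export
metricC1 <- function(cfg) (0.01 * cfg@maxVal)^2

#' @describeIn MetricConfig the SSIM stabilizer `(0.03 L)^2`
#' @export
metricC2 <- function(cfg) (0.03 * cfg@maxVal)^2

metricArray <- function(x) {
  if (is(x, "RasterImage")) toUint8(x)@pixels else x
}

checkSameShape <- function(x, y) {
  if (!identical(dim(x), dim(y)))
    stop("images must have identical dimensions: ",
         paste(dim(x), collapse = "x"), " vs ", paste(dim(y), collapse = "x"))
}

#' Mean squared error between two images
#'
#' The mean over all pixels and channels of squared differences, computed in
#' double precision on 8-bit values.
#'
#' @param x,y `RasterImage`s (or numeric arrays) of identical shape.
#' @return A single number.
#' @export
mseImage <- function(x, y) {
  ax <- metricArray(x); ay <- metricArray(y)
  checkSameShape(ax, ay)
  mean((ax - ay)^2)
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(MAX^2 / MSE)` in dB over all channels jointly, with
#' `MAX = 255` for 8-bit images and no border cropping. Identical images
#' (MSE = 0) return `Inf`.
#'
#' @param x,y `RasterImage`s of identical shape (converted to uint8).
#' @param cfg a [MetricConfig-class].
#' @return PSNR in dB.
#' @export
psnr <- function(x, y, cfg = MetricConfig()) {
  m <- mseImage(x, y)
  if (m == 0) return(Inf)
  10 * log10(cfg@maxVal^2 / m)
}

# one-channel global SSIM: single whole-image statistics (population moments),
# a literal transcription of the index definition
ssimGlobalChannel <- function(x, y, c1, c2) {
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

# 1-d Gaussian window, normalized
gaussWindow <- function(size, sigma) {
  t <- seq_len(size) - (size + 1) / 2
  w <- exp(-t^2 / (2 * sigma^2))
  w / sum(w)
}

# valid-mode separable window filtering of a matrix
windowFilter <- function(x, w) {
  n <- length(w)
  H <- nrow(x); W <- ncol(x)
  Mr <- matrix(0, H - n + 1, H)
  for (i in seq_len(H - n + 1)) Mr[i, i:(i + n - 1)] <- w
  Mc <- matrix(0, W - n + 1, W)
  for (j in seq_len(W - n + 1)) Mc[j, j:(j + n - 1)] <- w
  Mr %*% x %*% t(Mc)
}

ssimWindowedChannel <- function(x, y, c1, c2, w) {
  mx <- windowFilter(x, w); my <- windowFilter(y, w)
  vx <- windowFilter(x * x, w) - mx^2
  vy <- windowFilter(y * y, w) - my^2
  cxy <- windowFilter(x * y, w) - mx * my
  s <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  mean(s)
}

#' Structural similarity index
#'
#' Computed per channel and averaged. In `"windowed"` mode (default) local
#' statistics come from a Gaussian window (11x11, sigma 1.5) over the valid
#' interior, the field-standard estimator. In `"global"` mode the index is
#' evaluated once per channel from whole-image means, variances and
#' covariance — the literal single-statistics form of the definition.
#'
#' @param x,y `RasterImage`s of identical shape (converted to uint8 values).
#' @param cfg a [MetricConfig-class].
#' @return similarity in \[-1, 1\].
#' @export
ssim <- function(x, y, cfg = MetricConfig()) {
  ax <- metricArray(x); ay <- metricArray(y)
  checkSameShape(ax, ay)
  c1 <- metricC1(cfg); c2 <- metricC2(cfg)
  nch <- dim(ax)[3L]
  if (cfg@ssimMode == "global") {
    vals <- vapply(seq_len(nch), function(ch)
      ssimGlobalChannel(ax[, , ch], ay[, , ch], c1, c2), numeric(1))
  } else {
    n <- cfg@windowSize
    if (dim(ax)[1L] < n || dim(ax)[2L] < n)
      stop(sprintf("image %dx%d smaller than SSIM window %d",
                   dim(ax)[1L], dim(ax)[2L], n))
    w <- gaussWindow(n, cfg@windowSigma)
    vals <- vapply(seq_len(nch), function(ch)
      ssimWindowedChannel(ax[, , ch], ay[, , ch], c1, c2, w), numeric(1))
  }
  mean(vals)
}

checkCountRecords <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    stop("empty count record set")
  if (!all(c("yTrue", "yPred") %in% names(records)))
    stop("records must have columns yTrue and yPred")
  if (any(records$yTrue < 0) || any(records$yPred < 0))
    stop("counts must be >= 0")
  records
}

#' Mean absolute error of object counts
#'
#' @param records data.frame with columns `yTrue` (ground-truth count per
#'   image), `yPred` (predicted count), and optionally `imageId`.
#' @return MAE in objects per image.
#' @export
countMAE <- function(records) {
  records <- checkCountRecords(records)
  mean(abs(records$yPred - records$yTrue))
}

#' Root mean square error of object counts
#'
#' @inheritParams countMAE
#' @return RMSE in objects per image.
#' @export
countRMSE <- function(records) {
  records <- checkCountRecords(records)
  sqrt(mean((records$yPred - records$yTrue)^2))
}

#' Read count records from a CSV file
#'
#' Expects columns `image_id,y_true,y_pred` (the interchange format for
#' scoring an external counting model's predictions).
#'
#' @param path CSV file path.
#' @return data.frame with columns `imageId`, `yTrue`, `yPred`.
#' @export
readCountRecords <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("y_true", "y_pred") %in% names(tab)))
    stop("count CSV must have columns image_id,y_true,y_pred")
  data.frame(imageId = if (is.null(tab$image_id)) seq_len(nrow(tab))
             else tab$image_id,
             yTrue = tab$y_true, yPred = tab$y_pred,
             stringsAsFactors = FALSE)
}
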