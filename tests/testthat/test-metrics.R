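test_that("MSE matches hand computations and validates shapes", {
  a <- randomImage(4, 4, seed = 1)
  expect_equal(mseImage(a, a), 0)
  z <- RasterImage(array(0, c(3, 3, 3)), "uint8")
  w <- RasterImage(array(255, c(3, 3, 3)), "uint8")
  expect_equal(mseImage(z, w), 65025)
  x <- RasterImage(array(c(0, 10), c(2, 1, 1)), "uint8")
  y <- RasterImage(array(c(6, 2), c(2, 1, 1)), "uint8")
  expect_equal(mseImage(x, y), 50)    # (36 + 64) / 2
  expect_error(mseImage(a, z), "identical dimensions")
})

test_that("PSNR closed forms hold exactly", {
  a <- randomImage(5, 5, seed = 2)
  expect_identical(psnr(a, a), Inf)
  z <- RasterImage(array(0, c(4, 4, 3)), "uint8")
  w <- RasterImage(array(255, c(4, 4, 3)), "uint8")
  expect_equal(psnr(z, w), 0)
  base <- RasterImage(array(100, c(4, 4, 3)), "uint8")
  off16 <- RasterImage(array(116, c(4, 4, 3)), "uint8")
  expect_equal(psnr(base, off16), 10 * log10(65025 / 256), tolerance = 1e-12)
})

test_that("global SSIM matches its constants and the transcription oracle", {
  cfgG <- MetricConfig(ssimMode = "global")
  z <- RasterImage(array(0, c(4, 4, 3)), "uint8")
  w <- RasterImage(array(255, c(4, 4, 3)), "uint8")
  expect_equal(ssim(z, w, cfgG), 6.5025 / 65031.5025, tolerance = 1e-12)
  set.seed(9)
  x <- randomImage(8, 8, seed = 9, channels = 1)
  y <- randomImage(8, 8, seed = 10, channels = 1)
  expect_lt(abs(ssim(x, y, cfgG) -
                oracleSSIMGlobal(imgPixels(x), imgPixels(y))), 1e-12)
})

test_that("SSIM of identical non-constant images is 1 in both modes", {
  img <- randomImage(16, 16, seed = 4)
  expect_equal(ssim(img, img, MetricConfig(ssimMode = "global")), 1)
  expect_equal(ssim(img, img, MetricConfig()), 1)
})

test_that("windowed SSIM with a uniform window equals global on window-sized images", {
  # an 11x11 image with an 11x11 uniform window has one local statistic =
  # the global statistic; emulate the uniform window via sigma -> large
  x <- randomImage(11, 11, seed = 5, channels = 1)
  y <- randomImage(11, 11, seed = 6, channels = 1)
  near <- ssim(x, y, MetricConfig(ssimMode = "windowed", windowSize = 11,
                                  windowSigma = 1e6))
  glob <- ssim(x, y, MetricConfig(ssimMode = "global"))
  expect_equal(near, glob, tolerance = 1e-9)
})

test_that("windowed SSIM requires images at least as large as the window", {
  small <- randomImage(8, 8, seed = 7)
  expect_error(ssim(small, small, MetricConfig()), "smaller than SSIM window")
})

test_that("count MAE/RMSE match hand examples and reject empty input", {
  rec <- function(yt, yp) data.frame(yTrue = yt, yPred = yp)
  expect_equal(countMAE(rec(c(4, 4), c(4, 4))), 0)
  expect_equal(countRMSE(rec(c(4, 4), c(4, 4))), 0)
  expect_equal(countMAE(rec(c(4, 4), c(3, 5))), 1)
  expect_equal(countRMSE(rec(c(4, 4), c(3, 5))), 1)
  expect_equal(countMAE(rec(c(5, 5), c(0, 10))), 5)
  expect_equal(countRMSE(rec(c(5, 5), c(0, 10))), 5)
  expect_error(countMAE(rec(numeric(0), numeric(0))), "empty")
  expect_error(countMAE(rec(c(-1), c(0))), ">= 0")
})

test_that("RMSE dominates MAE on random record sets", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(1:30, 1)
    rec <- data.frame(yTrue = rpois(n, 20), yPred = rpois(n, 20))
    expect_gte(countRMSE(rec) + 1e-12, countMAE(rec))
  }
})

test_that("PSNR decreases as MSE increases", {
  base <- RasterImage(array(0, c(4, 4, 3)), "uint8")
  offsets <- c(4, 16, 64)
  ps <- vapply(offsets, function(o)
    psnr(base, RasterImage(array(o, c(4, 4, 3)), "uint8")), numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("count records round-trip through the CSV interchange format", {
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(image_id = c("a", "b"), y_true = c(4, 5),
                       y_pred = c(3, 7)), p, row.names = FALSE)
  rec <- readCountRecords(p)
  expect_equal(countMAE(rec), 1.5)
  expect_equal(rec$imageId, c("a", "b"))
})
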