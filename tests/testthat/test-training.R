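localDataset <- function(nTrain = 4, nTest = 1, size = 72, seed = 3,
                         envir = parent.frame()) {
  root <- withr::local_tempdir(.local_envir = envir)
  genSRDataset(nTrain, nTest, size = size, seed = seed, dir = root,
               overwrite = TRUE)
}

test_that("sampleBatch produces the contracted shapes and is seed-reproducible", {
  man <- localDataset()
  cfg <- TrainConfig(batchSize = 5L, patchSize = 64L, seed = 1L)
  deg <- DegradationConfig(scale = 2)
  set.seed(1)
  b1 <- sampleBatch(man, cfg, deg)
  expect_equal(dim(b1$hr), c(64L, 64L, 3L, 5L))
  expect_equal(dim(b1$lr), c(32L, 32L, 3L, 5L))
  b2 <- sampleBatch(man, cfg, deg)          # stream advances
  expect_false(identical(b1$hr, b2$hr))
  set.seed(1)
  b3 <- sampleBatch(man, cfg, deg)          # re-seeded run repeats
  expect_identical(b1$hr, b3$hr)
  expect_identical(b1$lr, b3$lr)
})

test_that("patches are cut from the degraded pair at aligned positions", {
  man <- localDataset(nTrain = 1, nTest = 1, size = 72, seed = 9)
  hr <- readRaster(manifestPaths(man, "train")[1])
  deg <- DegradationConfig(scale = 2)
  pair <- makeLRHRPair(hr, deg)
  imgs <- plantsr:::prepareTrainingImages(
    man, TrainConfig(patchSize = 64L), deg)
  expect_equal(length(imgs), 1L)
  expect_equal(imgs[[1]]$hr, imgPixels(pair$hr) / 255)
  expect_equal(imgs[[1]]$lr, imgPixels(pair$lr) / 255)
})

test_that("patch size must divide by the scale and tiny images are skipped", {
  man <- localDataset(nTrain = 2, nTest = 1, size = 48)
  expect_error(plantsr:::prepareTrainingImages(
    man, TrainConfig(patchSize = 63L), DegradationConfig(scale = 2)),
    "multiple of the scale")
  seen <- character(0)
  expect_error(
    withCallingHandlers(
      plantsr:::prepareTrainingImages(
        man, TrainConfig(patchSize = 64L), DegradationConfig(scale = 2)),
      warning = function(w) {
        seen <<- c(seen, conditionMessage(w))
        invokeRestart("muffleWarning")
      }),
    "no usable")
  expect_true(all(grepl("smaller than patch", seen)))
  expect_equal(length(seen), 2L)   # both undersized train images reported
})

test_that("L1 loss matches hand computations", {
  a <- array(runif(2 * 2 * 3 * 2), c(2, 2, 3, 2))
  expect_equal(l1Loss(a, a), 0)
  expect_equal(l1Loss(a + 0.1, a), 0.1)
  set.seed(2)
  b <- array(rnorm(8), c(2, 2, 2, 1))
  expect_equal(l1Loss(b, b * 0), mean(abs(b)))
  expect_error(l1Loss(a, array(0, c(2, 2, 3, 1))), "mismatch")
})

test_that("one epoch of k batches yields k loss entries and one eval record", {
  man <- localDataset()
  m <- tinyPlantSR(seed = 1)
  res <- trainSR(m, man, TrainConfig(batchSize = 2L, patchSize = 16L,
                                     batchesPerEpoch = 10L, epochs = 1L,
                                     seed = 0L),
                 DegradationConfig(scale = 2), evalSplit = "test",
                 metricCfg = MetricConfig(ssimMode = "global"))
  expect_equal(nrow(res$history), 10L)
  expect_equal(nrow(res$records), 1L)
  expect_true(res$records$isBest[1])
})

test_that("lr0 = 0 leaves the weights untouched", {
  man <- localDataset()
  m <- tinyPlantSR(seed = 6)
  res <- trainSR(m, man, TrainConfig(batchSize = 2L, patchSize = 16L,
                                     batchesPerEpoch = 3L, epochs = 1L,
                                     lr0 = 0, seed = 0L),
                 DegradationConfig(scale = 2),
                 metricCfg = MetricConfig(ssimMode = "global"))
  expect_identical(res$model@params, m@params)
})

test_that("a short optimization run decreases the training loss trend", {
  man <- localDataset(nTrain = 2, nTest = 1, size = 48, seed = 5)
  m <- buildPlantSR(PlantSRConfig(scale = 2, channels = 8, m = 0, n = 1,
                                  seReduction = 4), seed = 1)
  res <- trainSR(m, man, TrainConfig(batchSize = 4L, patchSize = 32L,
                                     batchesPerEpoch = 40L, epochs = 1L,
                                     lr0 = 1e-3, seed = 0L),
                 DegradationConfig(scale = 2),
                 metricCfg = MetricConfig(ssimMode = "global"))
  first <- median(head(res$history$loss, 10))
  last <- median(tail(res$history$loss, 10))
  expect_lt(last, first)
})

test_that("best-checkpoint selection is argmax PSNR with earliest-epoch ties", {
  rec <- data.frame(epoch = 1:4, testPsnr = c(20, 25, 25, 24))
  expect_equal(selectBestEpoch(rec), 2L)
  expect_equal(selectBestEpoch(data.frame(epoch = 1, testPsnr = 5)), 1L)
  expect_error(selectBestEpoch(data.frame(epoch = integer(0),
                                          testPsnr = numeric(0))), "no")
})

test_that("checkpoint directory receives per-epoch files, best and metrics", {
  man <- localDataset()
  ckdir <- withr::local_tempdir()
  m <- tinyPlantSR(seed = 2)
  res <- trainSR(m, man, TrainConfig(batchSize = 2L, patchSize = 16L,
                                     batchesPerEpoch = 2L, epochs = 2L,
                                     seed = 0L),
                 DegradationConfig(scale = 2), checkpointDir = ckdir,
                 metricCfg = MetricConfig(ssimMode = "global"))
  expect_true(file.exists(file.path(ckdir, "epoch_001.ckpt")))
  expect_true(file.exists(file.path(ckdir, "epoch_002.ckpt")))
  expect_true(file.exists(file.path(ckdir, "best.ckpt")))
  metrics <- read.csv(file.path(ckdir, "metrics.csv"))
  expect_equal(nrow(metrics), 2L)
  expect_equal(sum(metrics$isBest), 1L)
  best <- loadCheckpoint(file.path(ckdir, "best.ckpt"))
  expect_identical(best@params, res$model@params)
})

test_that("fine-tuning with zero epochs returns the pretrained weights", {
  man <- localDataset()
  m <- tinyPlantSR(seed = 3)
  ck <- withr::local_tempfile(fileext = ".ckpt")
  saveCheckpoint(m, ck)
  res <- fineTuneSR(ck, man, TrainConfig(batchSize = 2L, patchSize = 16L,
                                         batchesPerEpoch = 2L, epochs = 0L,
                                         seed = 0L),
                    metricCfg = MetricConfig(ssimMode = "global"))
  expect_identical(res$model@params, m@params)
  expect_identical(res$model@provenance, ck)
})

test_that("fine-tuning rejects a scale mismatch", {
  man <- localDataset()
  m <- tinyPlantSR(seed = 4)          # x2 checkpoint
  ck <- withr::local_tempfile(fileext = ".ckpt")
  saveCheckpoint(m, ck)
  expect_error(fineTuneSR(ck, man, TrainConfig(),
                          degradation = DegradationConfig(scale = 3)),
               "scale mismatch")
})

test_that("fine-tuning on a second domain reduces its loss below the frozen model", {
  # pretrain briefly on green foliage, then adapt to brown seed imagery
  manA <- localDataset(nTrain = 2, nTest = 1, size = 48, seed = 11)
  rootB <- withr::local_tempdir()
  withr::with_seed(1, {
    for (sp in c("train", "test")) {
      dir.create(file.path(rootB, sp))
      nn <- if (sp == "train") 2 else 1
      for (i in seq_len(nn))
        writeRaster(genPlantTexture(SynthSpec(48, 48, seed = 100 + i,
                                              palette = "brown")),
                    file.path(rootB, sp, sprintf("%s%d.png", sp, i)))
    }
  })
  manB <- loadManifest(rootB)
  cfg <- TrainConfig(batchSize = 4L, patchSize = 32L, batchesPerEpoch = 30L,
                     epochs = 1L, lr0 = 1e-3, seed = 0L)
  m <- buildPlantSR(PlantSRConfig(scale = 2, channels = 8, m = 0, n = 1,
                                  seReduction = 4), seed = 1)
  pre <- trainSR(m, manA, cfg, DegradationConfig(scale = 2),
                 metricCfg = MetricConfig(ssimMode = "global"))
  ck <- withr::local_tempfile(fileext = ".ckpt")
  saveCheckpoint(pre$model, ck)
  domainLoss <- function(model) {
    imgsB <- plantsr:::prepareTrainingImages(manB, cfg,
                                             DegradationConfig(scale = 2))
    mean(vapply(imgsB, function(im) {
      out <- plantsr:::netForward(model, im$lr)$out
      l1Loss(out, plantsr:::asBatch(im$hr))
    }, numeric(1)))
  }
  ft <- fineTuneSR(ck, manB, cfg, metricCfg = MetricConfig(ssimMode = "global"))
  expect_lt(domainLoss(ft$model), domainLoss(pre$model))
})

test_that("optimization at a practical rate overtakes the bicubic baseline", {
  # the generator must pose a learnable task: a small network trained
  # briefly (200 steps, lr 1e-3) reconstructs its training images better
  # than bicubic upscaling does
  root <- withr::local_tempdir()
  man <- genSRDataset(8, 2, size = 96, seed = 0, dir = root,
                      overwrite = TRUE)
  model <- buildPlantSR(PlantSRConfig(scale = 2, channels = 16, m = 1,
                                      n = 2, seReduction = 4), seed = 0)
  cfg <- TrainConfig(batchSize = 16L, patchSize = 64L, lr0 = 1e-3,
                     batchesPerEpoch = 100L, epochs = 2L, seed = 0L)
  res <- trainSR(model, man, cfg, DegradationConfig(scale = 2),
                 evalSplit = "train")
  bic <- evaluateModel("bicubic", man, "train", DegradationConfig(scale = 2))
  expect_gt(res$best$testPsnr, mean(bic$psnr))
})

test_that("non-finite loss aborts with a diagnostic", {
  man <- localDataset()
  m <- tinyPlantSR(seed = 7)
  m@params$head2$b[] <- Inf
  expect_error(trainSR(m, man, TrainConfig(batchSize = 1L, patchSize = 16L,
                                           batchesPerEpoch = 1L,
                                           epochs = 1L, seed = 0L),
                       DegradationConfig(scale = 2)),
               "non-finite loss")
})
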