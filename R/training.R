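#' Training configuration
#'
#' Defaults follow the published protocol: 32 patches of 64 px (high
#' resolution side) per batch, Adam at 1e-4, horizontal-flip augmentation.
#' For scale 3 use `patchSize = 63` so the patch divides by the scale.
#' `batchesPerEpoch` is a free knob: the published 38,997 batches per epoch
#' belongs to a 830-image corpus and synthetic fixtures use far fewer.
#'
#' @param batchSize patches per optimization step.
#' @param patchSize HR patch side in px.
#' @param lr0 initial Adam learning rate.
#' @param batchesPerEpoch optimization steps per epoch.
#' @param epochs epochs to train.
#' @param seed RNG seed for patch sampling and augmentation.
#' @param hflip horizontal-flip augmentation flag.
#' @param beta1,beta2,eps Adam hyper-parameters (framework defaults).
#' @return A [TrainConfig-class].
#' @export
TrainConfig <- function(batchSize = 32L, patchSize = 64L, lr0 = 1e-4,
                        batchesPerEpoch = 100L, epochs = 1L, seed = 0L,
                        hflip = TRUE, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  new("TrainConfig", batchSize = as.integer(batchSize),
      patchSize = as.integer(patchSize), lr0 = lr0,
      batchesPerEpoch = as.integer(batchesPerEpoch),
      epochs = as.integer(epochs), seed = as.integer(seed), hflip = hflip,
      beta1 = beta1, beta2 = beta2, eps = eps)
}

# Load the HR images of a split and precompute their bicubic LR counterparts
# (whole-image degradation, so patch statistics match full-image inference).
# Images smaller than the patch are skipped with a warning.
prepareTrainingImages <- function(manifest, cfg, degradation,
                                  split = "train") {
  if (cfg@patchSize %% degradation@scale != 0L)
    stop("patchSize must be a multiple of the scale")
  paths <- manifestPaths(manifest, split)
  imgs <- list()
  for (p in paths) {
    hr <- readRaster(p)
    if (imgHeight(hr) < cfg@patchSize || imgWidth(hr) < cfg@patchSize) {
      warning("skipping ", basename(p), ": smaller than patch size")
      next
    }
    pair <- makeLRHRPair(hr, degradation)
    imgs[[length(imgs) + 1L]] <- list(hr = toUnitFloatArray(pair$hr),
                                      lr = toUnitFloatArray(pair$lr))
  }
  if (length(imgs) == 0L)
    stop("no usable training images: all smaller than patch size ",
         cfg@patchSize)
  imgs
}

#' Sample one training batch of LR/HR patch pairs
#'
#' Uniformly samples an image, then a valid patch position; the HR patch has
#' side `cfg@patchSize` and the LR patch side `patchSize / scale`, cut from
#' the bicubic-downsampled image at the aligned position. Each pair is
#' independently flipped horizontally with probability 1/2 when
#' `cfg@hflip`. Consumes the current RNG stream, so a run seeded with
#' `set.seed()` is bit-reproducible.
#'
#' @param manifest a [DatasetManifest-class] (its train split is used).
#' @param cfg a [TrainConfig-class].
#' @param degradation a [DegradationConfig-class] fixing the scale.
#' @param images optional precomputed image cache (internal reuse).
#' @return list with arrays `lr` (`pl x pl x 3 x B`) and `hr`
#'   (`ps x ps x 3 x B`).
#' @export
sampleBatch <- function(manifest, cfg, degradation = DegradationConfig(),
                        images = NULL) {
  if (is.null(images))
    images <- prepareTrainingImages(manifest, cfg, degradation)
  s <- degradation@scale
  ps <- cfg@patchSize
  pl <- ps %/% s
  B <- cfg@batchSize
  lr <- array(0, c(pl, pl, 3L, B))
  hr <- array(0, c(ps, ps, 3L, B))
  for (b in seq_len(B)) {
    im <- images[[sample.int(length(images), 1L)]]
    dl <- dim(im$lr)
    li <- sample.int(dl[1L] - pl + 1L, 1L) - 1L
    lj <- sample.int(dl[2L] - pl + 1L, 1L) - 1L
    lp <- im$lr[li + seq_len(pl), lj + seq_len(pl), , drop = FALSE]
    hp <- im$hr[li * s + seq_len(ps), lj * s + seq_len(ps), , drop = FALSE]
    if (cfg@hflip && stats::runif(1) < 0.5) {
      lp <- lp[, rev(seq_len(pl)), , drop = FALSE]
      hp <- hp[, rev(seq_len(ps)), , drop = FALSE]
    }
    lr[, , , b] <- lp
    hr[, , , b] <- hp
  }
  list(lr = lr, hr = hr)
}

# evaluate a model on full HR images: degrade, reconstruct, score
evalOnImages <- function(model, hrImages, degradation, metricCfg) {
  rows <- lapply(seq_along(hrImages), function(i) {
    hr <- hrImages[[i]]
    if (!is(hr, "RasterImage")) hr <- RasterImage(hr, "unit")
    pair <- makeLRHRPair(toUint8(hr), degradation)
    sr <- toUint8(srForward(model, pair$lr))
    data.frame(imageId = i, psnr = psnr(sr, pair$hr, metricCfg),
               ssim = ssim(sr, pair$hr, metricCfg))
  })
  do.call(rbind, rows)
}

#' Select the best epoch record
#'
#' The best checkpoint is the argmax of evaluation PSNR with ties broken
#' toward the earliest epoch.
#'
#' @param records data.frame with columns `epoch` and `testPsnr`.
#' @return the index of the best row.
#' @export
selectBestEpoch <- function(records) {
  if (nrow(records) == 0L) stop("no checkpoint records")
  which(records$testPsnr == max(records$testPsnr))[1L]
}

#' Train a super-resolution model
#'
#' Patch-based training: each step samples `batchSize` LR/HR patch pairs,
#' runs the forward pass, and takes one Adam step on the mean-absolute (L1)
#' pixel loss. After each epoch the model is evaluated (PSNR/SSIM) on full
#' images of `evalSplit`, a checkpoint record is appended, and the weights
#' with the best evaluation PSNR so far are retained (ties to the earliest
#' epoch). Aborts with a diagnostic if the loss turns non-finite.
#'
#' @param model an [SRModel-class] (initial weights).
#' @param manifest a [DatasetManifest-class].
#' @param cfg a [TrainConfig-class].
#' @param degradation a [DegradationConfig-class]; its scale must match the
#'   model's.
#' @param evalSplit `"test"` or `"train"`; full images of this split are the
#'   per-epoch evaluation set.
#' @param metricCfg a [MetricConfig-class] for the per-epoch evaluation.
#' @param checkpointDir optional directory receiving `epoch_XXX.ckpt`,
#'   `best.ckpt` and `metrics.csv`.
#' @param verbose print per-epoch progress to stderr.
#' @param logEvery record the running loss every so many steps (history is
#'   kept per step regardless).
#' @return list with `model` (weights of the best epoch), `history`
#'   (per-step data.frame `step`, `epoch`, `loss`), `records` (per-epoch
#'   checkpoint records with `isBest`), and `best` (the best record).
#' @export
trainSR <- function(model, manifest, cfg = TrainConfig(),
                    degradation = DegradationConfig(scale = model@scale),
                    evalSplit = c("test", "train"),
                    metricCfg = MetricConfig(), checkpointDir = NULL,
                    verbose = FALSE, logEvery = 50L) {
  evalSplit <- match.arg(evalSplit)
  if (degradation@scale != model@scale)
    stop(sprintf("scale mismatch: model x%d vs degradation x%d",
                 model@scale, degradation@scale))
  set.seed(cfg@seed)
  trainImgs <- prepareTrainingImages(manifest, cfg, degradation, "train")
  evalImgs <- lapply(manifestPaths(manifest, evalSplit),
                     function(p) readRaster(p))
  if (length(evalImgs) == 0L) stop("evaluation set is empty")

  params <- model@params
  opt <- adamInit(params)
  history <- data.frame(step = integer(0), epoch = integer(0),
                        loss = numeric(0))
  records <- data.frame(epoch = integer(0), testPsnr = numeric(0),
                        testSsim = numeric(0), weightsPath = character(0),
                        isBest = logical(0), stringsAsFactors = FALSE)
  bestParams <- params
  step <- 0L
  for (ep in seq_len(cfg@epochs)) {
    for (bt in seq_len(cfg@batchesPerEpoch)) {
      batch <- sampleBatch(manifest, cfg, degradation, trainImgs)
      model@params <- params
      fw <- netForward(model, batch$lr, keep = TRUE)
      target <- if (upsamplingStyle(model) == "pre") batch$hr else batch$hr
      loss <- l1Loss(fw$out, target)
      if (!is.finite(loss))
        stop(sprintf("non-finite loss %.4g at epoch %d step %d; aborting",
                     loss, ep, bt))
      step <- step + 1L
      history <- rbind(history,
                       data.frame(step = step, epoch = ep, loss = loss))
      if (cfg@lr0 > 0) {
        grads <- netBackward(model, l1LossGrad(fw$out, target), fw)
        upd <- adamStep(params, grads, opt, cfg@lr0, cfg@beta1, cfg@beta2,
                        cfg@eps)
        params <- upd$params
        opt <- upd$state
      }
      if (verbose && step %% logEvery == 0L)
        message(sprintf("epoch %d step %d loss %.5f", ep, step, loss))
    }
    model@params <- params
    ev <- evalOnImages(model, evalImgs, degradation, metricCfg)
    wpath <- NA_character_
    if (!is.null(checkpointDir)) {
      dir.create(checkpointDir, recursive = TRUE, showWarnings = FALSE)
      wpath <- file.path(checkpointDir, sprintf("epoch_%03d.ckpt", ep))
      saveCheckpoint(model, wpath)
    }
    records <- rbind(records, data.frame(
      epoch = ep, testPsnr = mean(ev$psnr), testSsim = mean(ev$ssim),
      weightsPath = wpath, isBest = FALSE, stringsAsFactors = FALSE))
    ib <- selectBestEpoch(records)
    records$isBest <- seq_len(nrow(records)) == ib
    if (ib == nrow(records)) bestParams <- params
    if (verbose)
      message(sprintf("epoch %d eval PSNR %.3f dB SSIM %.4f", ep,
                      mean(ev$psnr), mean(ev$ssim)))
  }
  model@params <- if (nrow(records) > 0L) bestParams else params
  if (!is.null(checkpointDir)) {
    saveCheckpoint(model, file.path(checkpointDir, "best.ckpt"))
    utils::write.csv(records, file.path(checkpointDir, "metrics.csv"),
                     row.names = FALSE)
  }
  list(model = model, history = history, records = records,
       best = if (nrow(records) > 0L) records[records$isBest, ] else NULL)
}

#' Fine-tune a pretrained model on a new domain
#'
#' Identical to [trainSR()] but initialized from a pretrained checkpoint;
#' the parent checkpoint is recorded in the returned model's provenance.
#' This is the transfer-learning entry point used to specialize a generic
#' model to close-up images of a single crop.
#'
#' @param pretrained an [SRModel-class] or a checkpoint path.
#' @param manifest a [DatasetManifest-class] of the new domain.
#' @param cfg a [TrainConfig-class].
#' @param degradation a [DegradationConfig-class]; its scale must match the
#'   checkpoint's or an error is raised.
#' @param ... passed on to [trainSR()].
#' @return As [trainSR()].
#' @export
fineTuneSR <- function(pretrained, manifest, cfg = TrainConfig(),
                       degradation = NULL, ...) {
  parent <- NA_character_
  if (is.character(pretrained)) {
    parent <- pretrained
    pretrained <- loadCheckpoint(pretrained)
  }
  if (is.null(degradation))
    degradation <- DegradationConfig(scale = pretrained@scale)
  if (degradation@scale != pretrained@scale)
    stop(sprintf("scale mismatch: checkpoint x%d vs configured x%d",
                 pretrained@scale, degradation@scale))
  res <- trainSR(pretrained, manifest, cfg, degradation, ...)
  res$model@provenance <- parent
  res
}
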