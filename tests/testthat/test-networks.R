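test_that("convolution primitive matches a naive direct-sum oracle", {
  set.seed(3)
  x <- array(rnorm(5 * 4 * 2 * 2), c(5, 4, 2, 2))
  p <- plantsr:::convParam(2L, 3L, 3L)
  got <- plantsr:::convFwd(x, p)
  naive <- array(0, dim(got))
  for (n in 1:2) for (co in 1:3) for (i in 1:5) for (j in 1:4) {
    acc <- p$b[co]
    for (dj in 1:3) for (di in 1:3) for (c in 1:2) {
      ii <- i + di - 2; jj <- j + dj - 2
      if (ii >= 1 && ii <= 5 && jj >= 1 && jj <= 4)
        acc <- acc + p$W[co, c + 2 * ((di - 1) + 3 * (dj - 1))] * x[ii, jj, c, n]
    }
    naive[i, j, co, n] <- acc
  }
  expect_lt(max(abs(got - naive)), 1e-12)
})

test_that("analytic and finite-difference gradients agree for every architecture", {
  set.seed(7)
  models <- list(
    tinyPlantSR(seed = 2),
    buildSRCNN(2, seed = 2),
    buildVDSR(2, seed = 2),
    buildEDSR(3, seed = 2))
  modify <- function(tree, path, i, delta) {
    if (length(path) == 0) { tree[i] <- tree[i] + delta; return(tree) }
    tree[[path[[1]]]] <- modify(tree[[path[[1]]]], path[-1], i, delta)
    tree
  }
  # a representative weight leaf per architecture (path into the tree)
  leafOf <- list(
    plantsr = list("groups", 1L, "blocks", 2L, "se", "W1"),
    srcnn = list("conv2", "W"),
    vdsr = list("convs", 10L, "W"),
    edsr = list("blocks", 5L, "conv1", "W"))
  for (m in models) {
    x <- array(runif(5 * 5 * 3), c(5, 5, 3, 1))
    hr <- array(runif(5 * m@scale * 5 * m@scale * 3),
                c(5 * m@scale, 5 * m@scale, 3, 1))
    fw <- plantsr:::netForward(m, x, keep = TRUE)
    gr <- plantsr:::netBackward(m, plantsr:::l1LossGrad(fw$out, hr), fw)
    path <- leafOf[[m@name]]
    leafG <- gr; for (k in path) leafG <- leafG[[k]]
    i <- 3L
    eps <- 1e-6
    lossAt <- function(d) {
      mp <- m
      mp@params <- modify(mp@params, path, i, d)
      l1Loss(plantsr:::netForward(mp, x)$out, hr)
    }
    fd <- (lossAt(eps) - lossAt(-eps)) / (2 * eps)
    expect_lt(abs(fd - leafG[i]), 1e-7)
  }
})

test_that("RSEB with zero conv weights is the identity and counts 1210 params", {
  blk <- buildRSEB(8L, 4L)
  expect_equal(countParameters(blk), oracleRSEBParams(8L, 4L))
  expect_equal(countParameters(blk), 1210L)
  zero <- function(p) { p$W[] <- 0; p$b[] <- 0; p }
  blk$conv1 <- zero(blk$conv1); blk$conv2 <- zero(blk$conv2)
  x <- array(rnorm(6 * 6 * 8 * 2), c(6, 6, 8, 2))
  expect_identical(plantsr:::rsebFwd(x, blk)$y, x)
  # spatial dims preserved for any input
  x2 <- array(rnorm(3 * 9 * 8), c(3, 9, 8, 1))
  expect_equal(dim(plantsr:::rsebFwd(x2, buildRSEB(8L, 4L))$y), dim(x2))
  expect_error(buildRSEB(8L, 3L), "multiple")
})

test_that("zero-weight residual groups reduce the network to head(3*F0)", {
  m <- zeroAllGroups(buildPlantSR(PlantSRConfig(scale = 2, channels = 8,
                                                m = 1, n = 2,
                                                seReduction = 4), seed = 1))
  x <- array(runif(5 * 7 * 3), c(5, 7, 3, 1))
  fw <- plantsr:::plantsrFwd(m@params, m@config, x, keep = TRUE)
  F0 <- plantsr:::convFwd(x - 0.5, m@params$conv0)
  expect_identical(fw$F1, F0)
  expect_lt(max(abs(fw$S - 3 * F0)), 1e-12)
  # manual head evaluation on 3*F0 reproduces the network output
  U <- plantsr:::convFwd(3 * F0, m@params$head1)
  P <- plantsr:::pixelShuffleFwd(U, 2L)
  manual <- plantsr:::convFwd(P, m@params$head2) + 0.5
  expect_lt(max(abs(fw$out - manual)), 1e-12)
})

test_that("m = 0 degenerates the shallow stage to the identity", {
  m <- buildPlantSR(PlantSRConfig(scale = 2, channels = 8, m = 0, n = 1,
                                  seReduction = 4), seed = 1)
  x <- array(runif(4 * 4 * 3), c(4, 4, 3, 1))
  fw <- plantsr:::plantsrFwd(m@params, m@config, x, keep = TRUE)
  expect_identical(fw$F1, fw$F0)
  expect_equal(dim(fw$out)[1:2], c(8L, 8L))
})

test_that("output dims are exactly scale times input dims for all scales", {
  for (s in 2:4) {
    m <- buildPlantSR(PlantSRConfig(scale = s, channels = 8, m = 0, n = 1,
                                    seReduction = 4), seed = 1)
    e <- buildEDSR(s, seed = 1)
    for (hw in list(c(1L, 1L), c(3L, 5L), c(8L, 8L))) {
      x <- array(runif(prod(hw) * 3), c(hw, 3L, 1L))
      expect_identical(dim(plantsr:::netForward(m, x)$out)[1:2], hw * s)
      expect_identical(dim(plantsr:::netForward(e, x)$out)[1:2], hw * s)
    }
  }
  # the close-up workflow size: 185x270 at x3 -> 555x810
  m3 <- buildPlantSR(PlantSRConfig(scale = 3, channels = 8, m = 0, n = 1,
                                   seReduction = 4), seed = 1)
  x <- array(runif(185 * 270 * 3), c(185, 270, 3, 1))
  expect_identical(dim(plantsr:::netForward(m3, x)$out)[1:2], c(555L, 810L))
})

test_that("pre-upsampling baselines preserve the target dimensions", {
  x <- array(runif(6 * 7 * 3), c(6, 7, 3, 1))
  s <- buildSRCNN(2, seed = 1)
  v <- buildVDSR(2, seed = 1)
  expect_identical(dim(plantsr:::netForward(s, x)$out)[1:2], c(12L, 14L))
  expect_identical(dim(plantsr:::netForward(v, x)$out)[1:2], c(12L, 14L))
  expect_equal(upsamplingStyle(s), "pre")
  expect_equal(upsamplingStyle(buildEDSR(2)), "post")
})

test_that("zero-weight VDSR is exactly the bicubic-upscaled input", {
  v <- buildVDSR(2, seed = 1)
  for (i in seq_along(v@params$convs)) v@params$convs[[i]]$W[] <- 0
  x <- array(runif(4 * 4 * 3), c(4, 4, 3, 1))
  out <- plantsr:::netForward(v, x)$out
  expect_identical(out, plantsr:::preUpsample(x, 2L))
})

test_that("baseline parameter counts reproduce the published table exactly", {
  expect_identical(countParameters(buildSRCNN()), 69251L)
  expect_identical(countParameters(buildVDSR()), 667008L)
  expect_identical(countParameters(buildEDSR(2)), 1369859L)
  expect_identical(countParameters(buildEDSR(3)), 1554499L)
  expect_identical(countParameters(buildEDSR(4)), 1517571L)
  expect_error(buildEDSR(5), "unsupported scale")
})

test_that("PlantSR parameter counts match the analytic layer sum on a config grid", {
  grid <- expand.grid(C = c(8L, 16L), m = c(0L, 2L), n = c(1L, 3L),
                      r = c(4L, 8L), s = c(2L, 3L))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    mdl <- buildPlantSR(PlantSRConfig(scale = g$s, channels = g$C, m = g$m,
                                      n = g$n, seReduction = g$r), seed = 1)
    expect_identical(countParameters(mdl),
                     oraclePlantSRParams(g$C, g$m, g$n, g$r, g$s))
  }
  # additivity: one extra group adds exactly the per-group count
  base <- countParameters(buildPlantSR(PlantSRConfig(2, 8, 1, 1,
                                                     seReduction = 4)))
  plus <- countParameters(buildPlantSR(PlantSRConfig(2, 8, 1, 2,
                                                     seReduction = 4)))
  expect_identical(plus - base,
                   4L * oracleRSEBParams(8L, 4L) + oracleConvParams(8L, 8L, 3L))
})

test_that("forward passes are deterministic and reject non-RGB input", {
  m <- tinyPlantSR(seed = 3)
  x <- array(runif(6 * 6 * 3), c(6, 6, 3, 1))
  expect_identical(plantsr:::netForward(m, x)$out,
                   plantsr:::netForward(m, x)$out)
  g <- array(runif(6 * 6), c(6, 6, 1, 1))
  expect_error(plantsr:::netForward(m, g), "RGB")
})

test_that("srForward on a RasterImage returns a clamped unit-float image", {
  m <- tinyPlantSR(seed = 4)
  img <- randomImage(6, 6, seed = 11)
  sr <- srForward(m, img)
  expect_s4_class(sr, "RasterImage")
  expect_equal(imgRange(sr), "unit")
  expect_equal(dim(imgPixels(sr))[1:2], c(12L, 12L))
})

test_that("checkpoints round-trip weights, config and provenance", {
  m <- tinyPlantSR(seed = 5)
  p <- withr::local_tempfile(fileext = ".ckpt")
  saveCheckpoint(m, p)
  back <- loadCheckpoint(p)
  expect_identical(back@params, m@params)
  expect_identical(back@config, m@config)
  sidecar <- jsonlite::read_json(paste0(p, ".json"))
  expect_equal(sidecar$parameters, countParameters(m))
  expect_error(loadCheckpoint(file.path(tempdir(), "missing.ckpt")),
               "not found")
})
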