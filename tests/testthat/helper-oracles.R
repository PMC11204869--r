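# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately naive transcriptions, independent of the package's
# implementation paths.

# direct 2-D kernel-summation bicubic resize of a matrix (no separability):
# for each output pixel, sum kernel-weighted input samples over both axes
# with edge replication and per-pixel weight normalization; like the
# operator under test, the result is clamped to the unit range.
oracleBicubic <- function(X, outH, outW, a = -0.5, antialias = TRUE) {
  nIn <- dim(X)
  out <- matrix(0, outH, outW)
  axisTaps <- function(n, nOut, i) {
    zoom <- nOut / n
    ks <- if (antialias && zoom < 1) zoom else 1
    u <- (i - 0.5) / zoom + 0.5
    lo <- floor(u - 2 / ks)
    taps <- lo:(lo + ceiling(4 / ks) + 1)
    w <- ks * cubicWeight(ks * (u - taps), a)
    keep <- w != 0
    list(taps = pmin(pmax(taps[keep], 1), n), w = w[keep] / sum(w[keep]))
  }
  for (i in seq_len(outH)) {
    ti <- axisTaps(nIn[1], outH, i)
    for (j in seq_len(outW)) {
      tj <- axisTaps(nIn[2], outW, j)
      acc <- 0
      for (p in seq_along(ti$taps))
        for (q in seq_along(tj$taps))
          acc <- acc + ti$w[p] * tj$w[q] * X[ti$taps[p], tj$taps[q]]
      out[i, j] <- acc
    }
  }
  pmin(pmax(out, 0), 1)
}

# literal transcription of the similarity index from whole-image statistics
oracleSSIMGlobal <- function(x, y, L = 255) {
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  vx <- sum((x - mx)^2) / n; vy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

# analytic parameter-count oracles (layer-by-layer sums, with biases)
oracleConvParams <- function(cin, cout, k, bias = TRUE) {
  cout * cin * k * k + if (bias) cout else 0L
}
oracleRSEBParams <- function(C, r) {
  2L * oracleConvParams(C, C, 3L) +
    ((C %/% r) * C + C %/% r) + (C * (C %/% r) + C)
}
oraclePlantSRParams <- function(C, m, n, r, s, blocks = 4L) {
  perGroup <- blocks * oracleRSEBParams(C, r) + oracleConvParams(C, C, 3L)
  oracleConvParams(3L, C, 3L) + (m + n) * perGroup +
    oracleConvParams(C, C * s * s, 3L) + oracleConvParams(C, 3L, 3L)
}

# set every convolution weight and bias inside a residual group to zero
zeroGroup <- function(group) {
  zero <- function(p) { p$W[] <- 0; p$b[] <- 0; p }
  group$gconv <- zero(group$gconv)
  for (b in seq_along(group$blocks)) {
    group$blocks[[b]]$conv1 <- zero(group$blocks[[b]]$conv1)
    group$blocks[[b]]$conv2 <- zero(group$blocks[[b]]$conv2)
  }
  group
}

zeroAllGroups <- function(model) {
  for (g in seq_along(model@params$groups))
    model@params$groups[[g]] <- zeroGroup(model@params$groups[[g]])
  model
}

# tiny PlantSR used across architecture tests
tinyPlantSR <- function(scale = 2L, seed = 1L)
  buildPlantSR(PlantSRConfig(scale = scale, channels = 8L, m = 1L, n = 1L,
                             seReduction = 4L), seed = seed)

# single-group PlantSR with a small receptive field, for seam tests:
# 11 3x3 convolutions at LR resolution -> RF radius 11 LR px
shallowPlantSR <- function(scale = 2L, seed = 1L)
  buildPlantSR(PlantSRConfig(scale = scale, channels = 8L, m = 0L, n = 1L,
                             seReduction = 4L), seed = seed)

# LR rows/cols safely outside every interior tile edge: the tiling of a
# 96-px axis with 64-px tiles and 16-px overlap places tiles at 0 and 32,
# so interior edges sit at 32 and 64; a 13-px margin exceeds the shallow
# net's receptive field (11 LR px + 1 HR px from the final conv)
seamFreeMask96 <- function(scale) {
  keep <- rep(TRUE, 96)
  for (edge in c(32L, 64L)) {
    lo <- max(1L, edge - 13L + 1L)
    hi <- min(96L, edge + 13L)
    keep[lo:hi] <- FALSE
  }
  rep(keep, each = scale)
}

randomImage <- function(h, w, seed = 1L, channels = 3L) {
  set.seed(seed)
  RasterImage(array(sample(0:255, h * w * channels, replace = TRUE),
                    c(h, w, channels)), "uint8")
}
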