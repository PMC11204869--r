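#' Synthetic plant-texture specification
#'
#' @param height,width image size in px (>= 16).
#' @param seed RNG seed; the same spec always generates a bit-identical
#'   image.
#' @param nFrequencies number of random sinusoidal gratings summed into the
#'   texture; frequencies reach 0.45 cycles/px so the image keeps spectral
#'   energy well above the Nyquist limit of a downsampled grid (the regime
#'   where bicubic upscaling fails and super-resolution has something to
#'   learn).
#' @param edgeDensity approximate fraction of pixels on dark venation-like
#'   ridge lines.
#' @param palette `"green"` (foliage) or `"brown"` (seed/soil) base tones.
#' @return A [SynthSpec-class].
#' @export
SynthSpec <- function(height = 96L, width = 96L, seed = 0L,
                      nFrequencies = 24L, edgeDensity = 0.08,
                      palette = c("green", "brown")) {
  palette <- match.arg(palette)
  new("SynthSpec", height = as.integer(height), width = as.integer(width),
      seed = as.integer(seed), nFrequencies = as.integer(nFrequencies),
      edgeDensity = edgeDensity, palette = palette)
}

#' Generate a deterministic plant-like texture image
#'
#' The image is a sum of seeded random sinusoidal gratings (band-limited
#' fine texture reminiscent of venation), thresholded ridge lines (sharp
#' dark edges), and a smooth low-frequency illumination field, mapped
#' through a green- or brown-dominant palette to 8-bit RGB. It is fully
#' procedural: the same spec yields a bit-identical image on any platform.
#'
#' @param spec a [SynthSpec-class].
#' @return uint8 RGB `RasterImage`.
#' @export
genPlantTexture <- function(spec = SynthSpec()) {
  H <- spec@height; W <- spec@width
  withSeed(spec@seed, {
    ri <- matrix(seq_len(H), H, W)
    ci <- matrix(seq_len(W), H, W, byrow = TRUE)
    nf <- spec@nFrequencies
    freq <- stats::runif(nf, 0.03, 0.45)        # cycles per px
    theta <- stats::runif(nf, 0, pi)
    phase <- stats::runif(nf, 0, 2 * pi)
    amp <- 1 / (1 + 6 * freq)                   # mild 1/f decay
    tex <- matrix(0, H, W)
    for (k in seq_len(nf)) {
      fx <- freq[k] * cos(theta[k]); fy <- freq[k] * sin(theta[k])
      tex <- tex + amp[k] * sin(2 * pi * (fx * ci + fy * ri) + phase[k])
    }
    tex <- tex / max(abs(tex))
    # venation: dark ridges where a few low-frequency carriers cross zero
    ridges <- matrix(0, H, W)
    nr <- 3L
    rf <- stats::runif(nr, 0.02, 0.08)
    rt <- stats::runif(nr, 0, pi)
    rp <- stats::runif(nr, 0, 2 * pi)
    thr <- spec@edgeDensity * pi / 2            # |sin| < thr has that density
    for (k in seq_len(nr)) {
      fx <- rf[k] * cos(rt[k]); fy <- rf[k] * sin(rt[k])
      carrier <- sin(2 * pi * (fx * ci + fy * ri) + rp[k])
      ridges <- pmax(ridges, as.numeric(abs(carrier) < thr))
    }
    # smooth illumination
    ilf <- stats::runif(2, 0.004, 0.012)
    ilp <- stats::runif(2, 0, 2 * pi)
    illum <- 0.5 * sin(2 * pi * ilf[1] * ci + ilp[1]) +
      0.5 * sin(2 * pi * ilf[2] * ri + ilp[2])
    g <- 0.55 + 0.22 * tex + 0.10 * illum - 0.35 * ridges
    g <- pmin(pmax(g, 0), 1)
    tone <- stats::runif(3, -0.05, 0.05)
    chan <- if (spec@palette == "green") {
      list(r = 0.45 * g + 0.08, gg = 0.75 * g + 0.15, b = 0.30 * g + 0.05)
    } else {
      list(r = 0.70 * g + 0.15, gg = 0.50 * g + 0.10, b = 0.30 * g + 0.05)
    }
    px <- array(0, c(H, W, 3L))
    px[, , 1] <- pmin(pmax(chan$r + tone[1], 0), 1)
    px[, , 2] <- pmin(pmax(chan$gg + tone[2], 0), 1)
    px[, , 3] <- pmin(pmax(chan$b + tone[3], 0), 1)
    RasterImage(quantizeUnit(px), "uint8")
  })
}

#' Generate a synthetic SR dataset on disk
#'
#' Writes `nTrain` + `nTest` procedural plant textures as PNG under
#' `train/` and `test/` subdirectories of `dir`, with category labels
#' cycling over four pseudo-taxa encoded in the file names, and returns the
#' manifest. Regeneration with the same arguments reproduces byte-identical
#' files.
#'
#' @param nTrain,nTest image counts per split (>= 1).
#' @param size image side in px.
#' @param seed master seed; image i uses seed `seed + i * 9973`.
#' @param dir target directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return A [DatasetManifest-class].
#' @export
genSRDataset <- function(nTrain, nTest, size = 96L, seed = 0L,
                         dir = tempfile("srdata"), overwrite = FALSE) {
  if (nTrain < 1L || nTest < 1L) stop("nTrain and nTest must be >= 1")
  if (dir.exists(dir) && length(list.files(dir, recursive = TRUE)) > 0L &&
      !overwrite)
    stop("target directory not empty (use overwrite = TRUE): ", dir)
  taxa <- c("angiosperm", "gymnosperm", "fern", "bryophyte")
  writeSplit <- function(split, n, offset) {
    dd <- file.path(dir, split)
    dir.create(dd, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      idx <- offset + i
      img <- genPlantTexture(SynthSpec(size, size,
                                       seed = seed + idx * 9973L))
      writeRaster(img, file.path(dd, sprintf("img%03d_%s.png", idx,
                                             taxa[(idx - 1L) %% 4L + 1L])))
    }
  }
  writeSplit("train", nTrain, 0L)
  writeSplit("test", nTest, nTrain)
  loadManifest(dir)
}

#' Generate a counting scene with a known object count
#'
#' Places `nObjects` non-overlapping shaded disks (seed-like objects) on a
#' textured background by bounded rejection sampling; the ground-truth count
#' and center coordinates are returned alongside the image, so the counting
#' error harness can be exercised end-to-end without a detector.
#'
#' @param nObjects number of objects to place.
#' @param size image side in px.
#' @param radiusRange two-element range of disk radii in px.
#' @param seed RNG seed.
#' @return list with `image` (uint8 RGB `RasterImage`), `count`, and
#'   `centers` (data.frame `row`, `col`, `radius`, 0-based pixel centers).
#' @export
genCountingScene <- function(nObjects, size = 128L, radiusRange = c(4, 7),
                             seed = 0L) {
  withSeed(seed, {
    bg <- genPlantTexture(SynthSpec(size, size, seed = seed + 1L,
                                    palette = "green"))
    px <- bg@pixels / 255
    px <- 0.35 * px + 0.25                       # dim the background
    centers <- data.frame(row = numeric(0), col = numeric(0),
                          radius = numeric(0))
    maxTries <- 200L * nObjects
    tries <- 0L
    while (nrow(centers) < nObjects) {
      tries <- tries + 1L
      if (tries > maxTries)
        stop(sprintf(
          "could not place %d non-overlapping objects of radius %g-%g in %dpx",
          nObjects, radiusRange[1], radiusRange[2], size))
      r <- stats::runif(1, radiusRange[1], radiusRange[2])
      row <- stats::runif(1, r + 1, size - r - 1)
      col <- stats::runif(1, r + 1, size - r - 1)
      if (nrow(centers) > 0L) {
        d <- sqrt((centers$row - row)^2 + (centers$col - col)^2)
        if (any(d <= centers$radius + r + 1)) next
      }
      centers <- rbind(centers,
                       data.frame(row = row, col = col, radius = r))
    }
    ri <- matrix(seq_len(size), size, size)
    ci <- matrix(seq_len(size), size, size, byrow = TRUE)
    for (i in seq_len(nrow(centers))) {
      d2 <- (ri - centers$row[i] - 1)^2 + (ci - centers$col[i] - 1)^2
      mask <- d2 <= centers$radius[i]^2
      shade <- 1 - 0.6 * sqrt(pmin(d2 / centers$radius[i]^2, 1))
      for (ch in 1:3) {
        base <- c(0.85, 0.75, 0.45)[ch]          # seed-like tone
        plane <- px[, , ch]
        plane[mask] <- base * shade[mask]
        px[, , ch] <- plane
      }
    }
    list(image = RasterImage(quantizeUnit(pmin(pmax(px, 0), 1)), "uint8"),
         count = nObjects,
         centers = data.frame(row = centers$row - 1, col = centers$col - 1,
                              radius = centers$radius))
  })
}
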