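# Forward and backward passes for the four architectures. Activations are
# H x W x C x N unit-float arrays; inputs are mean-shifted by -0.5 and the
# network output shifted back (+0.5), except VDSR whose global residual adds
# the unshifted input. Backward passes mirror the forward caches exactly and
# return gradient trees parallel to the parameter trees.

rsebFwd <- function(x, p, keep = FALSE) {
  z1 <- convFwd(x, p$conv1)
  a1 <- reluFwd(z1)
  t3 <- convFwd(a1, p$conv2)
  se <- seFwd(t3, p$se)
  y <- x + se$y
  if (!keep) return(list(y = y))
  list(y = y, x = x, z1 = z1, a1 = a1, t3 = t3, se = se)
}

rsebBwd <- function(dy, p, cache) {
  seb <- seBwd(cache$t3, dy, p$se, cache$se)
  g2 <- convBwd(cache$a1, seb$dx, p$conv2)
  dz1 <- reluBwd(cache$z1, g2$dx)
  g1 <- convBwd(cache$x, dz1, p$conv1)
  list(dx = g1$dx + dy,
       grads = list(conv1 = list(W = g1$dW, b = g1$db),
                    conv2 = list(W = g2$dW, b = g2$db),
                    se = seb$grads))
}

rgFwd <- function(u, p, keep = FALSE) {
  v <- u
  caches <- vector("list", length(p$blocks))
  for (i in seq_along(p$blocks)) {
    r <- rsebFwd(v, p$blocks[[i]], keep)
    caches[[i]] <- r
    v <- r$y
  }
  w <- convFwd(v, p$gconv)
  y <- w + u
  if (!keep) return(list(y = y))
  list(y = y, blockCaches = caches, v = v)
}

rgBwd <- function(dy, p, cache) {
  gg <- convBwd(cache$v, dy, p$gconv)
  dv <- gg$dx
  blockGrads <- vector("list", length(p$blocks))
  for (i in rev(seq_along(p$blocks))) {
    r <- rsebBwd(dv, p$blocks[[i]], cache$blockCaches[[i]])
    blockGrads[[i]] <- r$grads
    dv <- r$dx
  }
  list(dx = dv + dy,
       grads = list(blocks = blockGrads,
                    gconv = list(W = gg$dW, b = gg$db)))
}

plantsrFwd <- function(params, cfg, x, keep = FALSE) {
  x0 <- x - 0.5
  F0 <- convFwd(x0, params$conv0)
  m <- cfg$m; n <- cfg$n
  cur <- F0
  gcaches <- vector("list", m + n)
  for (g in seq_len(m)) {
    r <- rgFwd(cur, params$groups[[g]], keep)
    gcaches[[g]] <- r
    cur <- r$y
  }
  F1 <- cur
  for (g in m + seq_len(n)) {
    r <- rgFwd(cur, params$groups[[g]], keep)
    gcaches[[g]] <- r
    cur <- r$y
  }
  FDF <- cur
  S <- F0 + F1 + FDF
  U <- convFwd(S, params$head1)
  P <- pixelShuffleFwd(U, cfg$scale)
  out <- convFwd(P, params$head2) + 0.5
  if (!keep) return(list(out = out))
  list(out = out, x0 = x0, F0 = F0, F1 = F1, S = S, P = P,
       gcaches = gcaches)
}

plantsrBwd <- function(dout, params, cfg, cache) {
  g2 <- convBwd(cache$P, dout, params$head2)
  dU <- pixelShuffleBwd(g2$dx, cfg$scale)
  g1 <- convBwd(cache$S, dU, params$head1)
  dS <- g1$dx
  m <- cfg$m; n <- cfg$n
  groupGrads <- vector("list", m + n)
  g <- dS                                  # gradient wrt FDF
  for (i in rev(m + seq_len(n))) {
    r <- rgBwd(g, params$groups[[i]], cache$gcaches[[i]])
    groupGrads[[i]] <- r$grads
    g <- r$dx
  }
  g <- g + dS                              # add direct F1 contribution
  for (i in rev(seq_len(m))) {
    r <- rgBwd(g, params$groups[[i]], cache$gcaches[[i]])
    groupGrads[[i]] <- r$grads
    g <- r$dx
  }
  dF0 <- g + dS                            # add direct F0 contribution
  g0 <- convBwd(cache$x0, dF0, params$conv0)
  list(grads = list(conv0 = list(W = g0$dW, b = g0$db),
                    groups = groupGrads,
                    head1 = list(W = g1$dW, b = g1$db),
                    head2 = list(W = g2$dW, b = g2$db)))
}

srcnnFwd <- function(params, x, keep = FALSE) {
  x0 <- x - 0.5
  z1 <- convFwd(x0, params$conv1); a1 <- reluFwd(z1)
  z2 <- convFwd(a1, params$conv2); a2 <- reluFwd(z2)
  out <- convFwd(a2, params$conv3) + 0.5
  if (!keep) return(list(out = out))
  list(out = out, x0 = x0, z1 = z1, a1 = a1, z2 = z2, a2 = a2)
}

srcnnBwd <- function(dout, params, cache) {
  g3 <- convBwd(cache$a2, dout, params$conv3)
  dz2 <- reluBwd(cache$z2, g3$dx)
  g2 <- convBwd(cache$a1, dz2, params$conv2)
  dz1 <- reluBwd(cache$z1, g2$dx)
  g1 <- convBwd(cache$x0, dz1, params$conv1)
  list(grads = list(conv1 = list(W = g1$dW, b = g1$db),
                    conv2 = list(W = g2$dW, b = g2$db),
                    conv3 = list(W = g3$dW, b = g3$db)))
}

vdsrFwd <- function(params, x, keep = FALSE) {
  nl <- length(params$convs)
  acts <- vector("list", nl)               # pre-activations per layer
  ins <- vector("list", nl)                # layer inputs
  cur <- x - 0.5
  for (i in seq_len(nl)) {
    ins[[i]] <- cur
    z <- convFwd(cur, params$convs[[i]])
    acts[[i]] <- z
    cur <- if (i < nl) reluFwd(z) else z
  }
  out <- cur + x                           # global residual
  if (!keep) return(list(out = out))
  list(out = out, ins = ins, acts = acts)
}

vdsrBwd <- function(dout, params, cache) {
  nl <- length(params$convs)
  grads <- vector("list", nl)
  g <- dout
  for (i in rev(seq_len(nl))) {
    if (i < nl) g <- reluBwd(cache$acts[[i]], g)
    cb <- convBwd(cache$ins[[i]], g, params$convs[[i]])
    grads[[i]] <- list(W = cb$dW, b = cb$db)
    g <- cb$dx
  }
  list(grads = list(convs = grads))
}

edsrFwd <- function(params, cfg, x, keep = FALSE) {
  x0 <- x - 0.5
  h <- convFwd(x0, params$head)
  cur <- h
  bcaches <- vector("list", length(params$blocks))
  for (i in seq_along(params$blocks)) {
    bp <- params$blocks[[i]]
    z1 <- convFwd(cur, bp$conv1)
    a1 <- reluFwd(z1)
    z2 <- convFwd(a1, bp$conv2)
    bcaches[[i]] <- list(x = cur, z1 = z1, a1 = a1)
    cur <- cur + z2
  }
  B <- convFwd(cur, params$convB)
  feat <- B + h                            # global skip
  upins <- vector("list", length(params$up))
  for (i in seq_along(params$up)) {
    upins[[i]] <- feat
    u <- convFwd(feat, params$up[[i]])
    feat <- pixelShuffleFwd(u, cfg$stages[i])
  }
  out <- convFwd(feat, params$convOut) + 0.5
  if (!keep) return(list(out = out))
  list(out = out, x0 = x0, bcaches = bcaches, resOut = cur,
       upins = upins, featOut = feat)
}

edsrBwd <- function(dout, params, cfg, cache) {
  go <- convBwd(cache$featOut, dout, params$convOut)
  g <- go$dx
  upGrads <- vector("list", length(params$up))
  for (i in rev(seq_along(params$up))) {
    du <- pixelShuffleBwd(g, cfg$stages[i])
    cb <- convBwd(cache$upins[[i]], du, params$up[[i]])
    upGrads[[i]] <- list(W = cb$dW, b = cb$db)
    g <- cb$dx
  }
  # g is gradient wrt feat = convB(resOut) + h
  gb <- convBwd(cache$resOut, g, params$convB)
  dcur <- gb$dx
  dh <- g                                  # global-skip branch
  blockGrads <- vector("list", length(params$blocks))
  for (i in rev(seq_along(params$blocks))) {
    bc <- cache$bcaches[[i]]
    bp <- params$blocks[[i]]
    c2 <- convBwd(bc$a1, dcur, bp$conv2)
    dz1 <- reluBwd(bc$z1, c2$dx)
    c1 <- convBwd(bc$x, dz1, bp$conv1)
    blockGrads[[i]] <- list(conv1 = list(W = c1$dW, b = c1$db),
                            conv2 = list(W = c2$dW, b = c2$db))
    dcur <- dcur + c1$dx
  }
  dh <- dh + dcur
  ghead <- convBwd(cache$x0, dh, params$head)
  list(grads = list(head = list(W = ghead$dW, b = ghead$db),
                    blocks = blockGrads,
                    convB = list(W = gb$dW, b = gb$db),
                    up = upGrads,
                    convOut = list(W = go$dW, b = go$db)))
}

# bicubic pre-upsampling for SRCNN/VDSR, applied per batch item (no clamp)
preUpsample <- function(x, s, a = -0.5) {
  d <- dim(x)
  out <- array(0, c(d[1L] * s, d[2L] * s, d[3L], d[4L]))
  Mr <- resampleMatrix(d[1L], d[1L] * s, a, FALSE)
  Mc <- resampleMatrix(d[2L], d[2L] * s, a, FALSE)
  for (n in seq_len(d[4L]))
    for (ch in seq_len(d[3L]))
      out[, , ch, n] <- Mr %*% x[, , ch, n] %*% t(Mc)
  out
}

#' @describeIn srForward whether a model refines a bicubic-upscaled input
#'   (`"pre"`) or upscales at the end of the network (`"post"`)
#' @export
upsamplingStyle <- function(model) {
  if (model@name %in% c("srcnn", "vdsr")) "pre" else "post"
}

# full forward pass on a batch array; handles pre-upsampling internally
netForward <- function(model, x, keep = FALSE) {
  x <- asBatch(x)
  if (dim(x)[3L] != 3L)
    stop("network input must be RGB (3 channels), got ", dim(x)[3L])
  if (upsamplingStyle(model) == "pre") x <- preUpsample(x, model@scale)
  switch(model@name,
    plantsr = plantsrFwd(model@params, model@config, x, keep),
    srcnn = srcnnFwd(model@params, x, keep),
    vdsr = vdsrFwd(model@params, x, keep),
    edsr = edsrFwd(model@params, model@config, x, keep))
}

netBackward <- function(model, dout, cache) {
  switch(model@name,
    plantsr = plantsrBwd(dout, model@params, model@config, cache),
    srcnn = srcnnBwd(dout, model@params, cache),
    vdsr = vdsrBwd(dout, model@params, cache),
    edsr = edsrBwd(dout, model@params, model@config, cache))$grads
}

#' Super-resolve an image or batch with a network
#'
#' Runs the network forward pass. For a `RasterImage` input the result is a
#' unit-float `RasterImage` with values clamped to \[0, 1\] (convert with
#' [toUint8()] for export); output dimensions are exactly `scale` times the
#' input dimensions. For a raw numeric array (`H x W x 3` or
#' `H x W x 3 x N`) the unclamped network output is returned, as used for
#' loss computation during training.
#'
#' @param model an [SRModel-class].
#' @param x a `RasterImage` or a unit-float numeric array.
#' @return `RasterImage` or numeric array of the same kind as the input.
#' @export
srForward <- function(model, x) {
  if (is(x, "RasterImage")) {
    if (imgChannels(x) != 3L) stop("network input must be RGB")
    arr <- toUnitFloatArray(x)
    out <- netForward(model, arr)$out
    out <- pmin(pmax(out, 0), 1)
    dim(out) <- dim(out)[1:3]
    return(RasterImage(out, "unit"))
  }
  netForward(model, x)$out
}

toUnitFloatArray <- function(img) {
  if (img@range == "uint8") img@pixels / 255 else img@pixels
}
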