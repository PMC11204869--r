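# Internal neural-network primitives: thin R wrappers over the compiled
# conv kernels, SE-attention, pixel shuffle, parameter initialization and
# the Adam optimizer. Activations are H x W x C x N arrays of doubles.

asBatch <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

# conv parameter container: W is Cout x (Cin*k*k), column index
# cin + Cin*(di + k*dj); b has length Cout (all zeros if bias = FALSE).
# `scale` shrinks the He init: residual super-resolution stacks are trained
# from near-identity initializations (zero residual-branch exits, 0.1-scaled
# heads), otherwise activation variance grows with every skip connection.
convParam <- function(cin, cout, k, init = c("he", "zero"), bias = TRUE,
                      scale = 1) {
  init <- match.arg(init)
  nw <- cout * cin * k * k
  W <- if (init == "zero") matrix(0, cout, cin * k * k)
  else matrix(stats::rnorm(nw, sd = scale * sqrt(2 / (cin * k * k))),
              cout, cin * k * k)
  list(W = W, b = numeric(cout), k = k, bias = bias)
}

convFwd <- function(x, p) {
  cpp_conv_fwd(x, dim(x), p$W, p$b, p$k)
}

convBwd <- function(x, dy, p) {
  g <- cpp_conv_bwd(x, dim(x), dy, p$W, p$k)
  if (!p$bias) g$db <- numeric(length(g$db))
  g
}

reluFwd <- function(x) {
  x[x < 0] <- 0
  x
}

# mask-free backward: uses pre-activation z
reluBwd <- function(z, dy) dy * (z > 0)

seParam <- function(C, r) {
  cr <- C %/% r
  list(W1 = matrix(stats::rnorm(cr * C, sd = sqrt(2 / C)), cr, C),
       b1 = numeric(cr),
       W2 = matrix(stats::rnorm(C * cr, sd = sqrt(1 / cr)), C, cr),
       b2 = numeric(C))
}

# squeeze-and-excitation: global average pool -> C/r bottleneck (ReLU) ->
# C gate (sigmoid) -> channel-wise rescale
seFwd <- function(x, p) {
  d <- dim(x)
  HW <- d[1L] * d[2L]
  xm <- x; dim(xm) <- c(HW, d[3L] * d[4L])
  s <- matrix(colMeans(xm), d[3L], d[4L])      # C x N
  z1 <- p$W1 %*% s + p$b1
  a1 <- pmax(z1, 0)
  z2 <- p$W2 %*% a1 + p$b2
  g <- 1 / (1 + exp(-z2))                      # C x N gates
  y <- x * rep(as.vector(g), each = HW)
  dim(y) <- d
  list(y = y, s = s, z1 = z1, a1 = a1, g = g)
}

seBwd <- function(x, dy, p, cache) {
  d <- dim(x)
  HW <- d[1L] * d[2L]
  prod <- x * dy; dim(prod) <- c(HW, d[3L] * d[4L])
  dg <- matrix(colSums(prod), d[3L], d[4L])
  dx1 <- dy * rep(as.vector(cache$g), each = HW)
  dz2 <- dg * cache$g * (1 - cache$g)
  dW2 <- dz2 %*% t(cache$a1)
  db2 <- rowSums(dz2)
  da1 <- t(p$W2) %*% dz2
  dz1 <- da1 * (cache$z1 > 0)
  dW1 <- dz1 %*% t(cache$s)
  db1 <- rowSums(dz1)
  ds <- t(p$W1) %*% dz1                        # C x N
  dx2 <- rep(as.vector(ds) / HW, each = HW)
  dx <- dx1 + dx2
  dim(dx) <- d
  list(dx = dx,
       grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

# pixel shuffle: (H, W, C*s^2, N) -> (H*s, W*s, C, N).
# out[(i-1)s+di, (j-1)s+dj, c] = in[i, j, (c-1)s^2 + (di-1)s + dj].
pixelShuffleIndex <- local({
  cache <- new.env(parent = emptyenv())
  function(H, W, Cs2, N, s) {
    key <- paste(H, W, Cs2, N, s, sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    C <- Cs2 %/% (s * s)
    Hs <- H * s; Ws <- W * s
    oh <- rep.int(seq_len(Hs), Ws * C * N)
    ow <- rep.int(rep(seq_len(Ws), each = Hs), C * N)
    oc <- rep.int(rep(seq_len(C), each = Hs * Ws), N)
    on <- rep(seq_len(N), each = Hs * Ws * C)
    i <- (oh - 1L) %/% s + 1L; di <- (oh - 1L) %% s
    j <- (ow - 1L) %/% s + 1L; dj <- (ow - 1L) %% s
    sc <- (oc - 1L) * s * s + di * s + dj + 1L
    idx <- i + H * (j - 1L) + H * W * (sc - 1L) + H * W * Cs2 * (on - 1L)
    cache[[key]] <- idx
    idx
  }
})

pixelShuffleFwd <- function(x, s) {
  d <- dim(x)
  stopifnot(d[3L] %% (s * s) == 0L)
  idx <- pixelShuffleIndex(d[1L], d[2L], d[3L], d[4L], s)
  y <- x[idx]
  dim(y) <- c(d[1L] * s, d[2L] * s, d[3L] %/% (s * s), d[4L])
  y
}

pixelShuffleBwd <- function(dy, s) {
  d <- dim(dy)
  H <- d[1L] %/% s; W <- d[2L] %/% s; Cs2 <- d[3L] * s * s
  idx <- pixelShuffleIndex(H, W, Cs2, d[4L], s)
  dx <- numeric(length(dy))
  dx[idx] <- dy
  dim(dx) <- c(H, W, Cs2, d[4L])
  dx
}

# ---- parameter-tree helpers -------------------------------------------------

isLeafParam <- function(x) is.numeric(x)

# apply f to every numeric leaf of two parallel trees, returning a tree;
# sublists may be unnamed (layer stacks), leaves named k/bias are metadata
paramMap2 <- function(a, b, f) {
  if (isLeafParam(a)) return(f(a, b))
  out <- a
  nms <- names(a)
  for (i in seq_along(a)) {
    nm <- if (is.null(nms)) "" else nms[i]
    if (nm %in% c("k", "bias")) next
    out[[i]] <- paramMap2(a[[i]], b[[i]], f)
  }
  out
}

paramLeafCount <- function(a) {
  if (isLeafParam(a)) return(length(a))
  tot <- 0
  nms <- names(a)
  for (i in seq_along(a)) {
    nm <- if (is.null(nms)) "" else nms[i]
    if (nm %in% c("k", "bias")) next
    if (nm == "b" && identical(a$bias, FALSE)) next
    tot <- tot + paramLeafCount(a[[i]])
  }
  tot
}

zeroLike <- function(a) paramMap2(a, a, function(x, y) x * 0)

# ---- Adam -------------------------------------------------------------------

adamInit <- function(params) {
  list(m = zeroLike(params), v = zeroLike(params), t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- paramMap2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- paramMap2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mh <- paramMap2(state$m, state$m, function(m, .) m / bc1)
  vh <- paramMap2(state$v, state$v, function(v, .) v / bc2)
  upd <- paramMap2(mh, vh, function(m, v) m / (sqrt(v) + eps))
  params <- paramMap2(params, upd, function(p, u) p - lr * u)
  list(params = params, state = state)
}

# ---- loss -------------------------------------------------------------------

#' Mean absolute (L1) pixel loss
#'
#' The training objective: the mean over batch, pixels and channels of
#' `|sr - hr|`, computed in unit-float space.
#'
#' @param sr,hr numeric arrays of identical shape (batches or single images).
#' @return A single number.
#' @export
l1Loss <- function(sr, hr) {
  if (!identical(dim(sr), dim(hr)))
    stop("shape mismatch between sr and hr batches")
  mean(abs(sr - hr))
}

l1LossGrad <- function(sr, hr) {
  sign(sr - hr) / length(sr)
}

# run code with a temporary RNG seed, restoring the caller's RNG state
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
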