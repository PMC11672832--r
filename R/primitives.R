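# Differentiable primitives ----------------------------------------------
#
# Every primitive returns list(y = output, cache = ...) and has a matching
# *_bw(cache, dy) that returns the input gradient (and parameter gradients
# where applicable). Arrays are N x C x H x W throughout. These are the only
# places the chain rule is written down; composite blocks and the graph
# executor just compose them in reverse.

same_pad <- function(k) (k - 1L) %/% 2L

conv_fw <- function(x, w, b = NULL, stride = 1L, pad = NULL, groups = 1L) {
  if (is.null(pad)) pad <- same_pad(dim(w)[3L])
  y <- cpp_conv2d_fw(x, w, b, as.integer(stride), as.integer(pad),
                     as.integer(groups))
  if (isTRUE(.prof$active)) {
    dw <- dim(w); dy <- dim(y)
    prof_add(2 * dw[3L] * dw[4L] * dw[2L] * dw[1L] * dy[3L] * dy[4L] * dy[1L])
  }
  list(y = y, cache = list(x = x, w = w, stride = as.integer(stride),
                           pad = as.integer(pad), groups = as.integer(groups),
                           has_bias = !is.null(b)))
}

conv_bw <- function(cache, dy, need_dx = TRUE) {
  r <- cpp_conv2d_bw(cache$x, cache$w, dy, cache$stride, cache$pad,
                     cache$groups, need_dx, cache$has_bias)
  list(dx = if (need_dx) r$dx else NULL, dw = r$dw,
       db = if (cache$has_bias) r$db else NULL)
}

# Batch normalization. Per-channel statistics over (N, H, W); in training
# mode batch statistics are used and running statistics updated in the
# returned cache; in eval mode the provided running statistics are used.
bn_fw <- function(x, gamma, beta, rm, rv, training, momentum = 0.03,
                  eps = 1e-5, unbias = TRUE) {
  d <- dim(x); N <- d[1L]; C <- d[2L]; S <- d[3L] * d[4L]
  x3 <- x; dim(x3) <- c(N, C, S)
  if (training) {
    m <- rowMeans(colMeans(x3))               # colMeans -> C x S, then over S
    xc <- x3 - rep(m, each = N)
    v <- rowMeans(colMeans(xc * xc))
    corr <- if (unbias) (N * S) / max(1, N * S - 1) else 1
    rm_new <- (1 - momentum) * rm + momentum * m
    rv_new <- (1 - momentum) * rv + momentum * v * corr
  } else {
    m <- rm; v <- rv; rm_new <- rm; rv_new <- rv
  }
  invstd <- 1 / sqrt(v + eps)
  scale <- gamma * invstd
  shift <- beta - m * scale
  y <- x3 * rep(scale, each = N) + rep(shift, each = N)
  dim(y) <- d
  list(y = y,
       cache = list(x3 = x3, m = m, invstd = invstd, gamma = gamma,
                    N = N, C = C, S = S, d = d, training = training),
       rm = rm_new, rv = rv_new)
}

bn_bw <- function(cache, dy) {
  N <- cache$N; C <- cache$C; S <- cache$S
  dy3 <- dy; dim(dy3) <- c(N, C, S)
  xhat <- (cache$x3 - rep(cache$m, each = N)) * rep(cache$invstd, each = N)
  dgamma <- rowSums(colSums(dy3 * xhat))
  dbeta <- rowSums(colSums(dy3))
  if (cache$training) {
    mdy <- dbeta / (N * S)
    mdyx <- dgamma / (N * S)
    dx <- rep(cache$gamma * cache$invstd, each = N) *
      (dy3 - rep(mdy, each = N) - xhat * rep(mdyx, each = N))
  } else {
    dx <- dy3 * rep(cache$gamma * cache$invstd, each = N)
  }
  dim(dx) <- cache$d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Group normalization: per-sample, per-group moments over (C/G, H, W).
gn_fw <- function(x, gamma, beta, groups, eps = 1e-5) {
  d <- dim(x); N <- d[1L]; C <- d[2L]; S <- d[3L] * d[4L]
  G <- as.integer(groups); Cg <- C %/% G
  if (Cg * G != C) stop("GroupNorm: ", C, " channels not divisible by ", G, " groups")
  # reorder to (Cg, S, N, G) so each column of the matrix is one (n, g) group
  x4 <- x; dim(x4) <- c(N, Cg, G, S)
  xp <- aperm(x4, c(2L, 4L, 1L, 3L))          # Cg, S, N, G
  dim(xp) <- c(Cg * S, N * G)
  m <- colMeans(xp)
  xc <- xp - rep(m, each = Cg * S)
  v <- colMeans(xc * xc)
  invstd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(invstd, each = Cg * S)
  # back to (N, C, S) then scale per channel
  xh <- xhat; dim(xh) <- c(Cg, S, N, G)
  xh <- aperm(xh, c(3L, 1L, 4L, 2L))          # N, Cg, G, S
  dim(xh) <- c(N, C, S)
  y <- xh * rep(gamma, each = N) + rep(beta, each = N)
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, invstd = invstd, gamma = gamma,
                           N = N, C = C, S = S, G = G, Cg = Cg, d = d))
}

gn_bw <- function(cache, dy) {
  N <- cache$N; C <- cache$C; S <- cache$S; G <- cache$G; Cg <- cache$Cg
  dy3 <- dy; dim(dy3) <- c(N, C, S)
  # xhat in (N,C,S) order for the channel-wise parameter grads
  xh <- cache$xhat; dim(xh) <- c(Cg, S, N, G)
  xh_ncs <- aperm(xh, c(3L, 1L, 4L, 2L)); dim(xh_ncs) <- c(N, C, S)
  dgamma <- rowSums(colSums(dy3 * xh_ncs))
  dbeta <- rowSums(colSums(dy3))
  # dyhat in group layout
  dyh <- dy3 * rep(cache$gamma, each = N)
  dim(dyh) <- c(N, Cg, G, S)
  dyh <- aperm(dyh, c(2L, 4L, 1L, 3L)); dim(dyh) <- c(Cg * S, N * G)
  mdy <- colMeans(dyh)
  mdyx <- colMeans(dyh * cache$xhat)
  dxg <- rep(cache$invstd, each = Cg * S) *
    (dyh - rep(mdy, each = Cg * S) - cache$xhat * rep(mdyx, each = Cg * S))
  dim(dxg) <- c(Cg, S, N, G)
  dx <- aperm(dxg, c(3L, 1L, 4L, 2L))
  dim(dx) <- cache$d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Activations -------------------------------------------------------------

silu_fw <- function(x) {
  s <- 1 / (1 + exp(-x))
  list(y = x * s, cache = list(x = x, s = s))
}
silu_bw <- function(cache, dy) dy * (cache$s * (1 + cache$x * (1 - cache$s)))

relu6_fw <- function(x) {
  y <- pmin(pmax(x, 0), 6)
  list(y = array(y, dim(x)), cache = (x > 0 & x < 6))
}
relu6_bw <- function(cache, dy) dy * cache

sigmoid_fw <- function(x) {
  s <- 1 / (1 + exp(-x))
  list(y = s, cache = s)
}
sigmoid_bw <- function(cache, dy) dy * cache * (1 - cache)

act_fw <- function(x, act) {
  switch(act,
         silu = silu_fw(x),
         relu6 = relu6_fw(x),
         sigmoid = sigmoid_fw(x),
         none = list(y = x, cache = NULL),
         stop("unknown activation: ", act))
}
act_bw <- function(cache, dy, act) {
  switch(act,
         silu = silu_bw(cache, dy),
         relu6 = relu6_bw(cache, dy),
         sigmoid = sigmoid_bw(cache, dy),
         none = dy)
}

# Pooling / resampling ----------------------------------------------------

maxpool_fw <- function(x, k, stride = 1L, pad = NULL) {
  if (is.null(pad)) pad <- same_pad(k)
  r <- cpp_maxpool_fw(x, as.integer(k), as.integer(stride), as.integer(pad))
  list(y = r$y, cache = list(idx = r$idx, xdim = dim(x)))
}
maxpool_bw <- function(cache, dy) cpp_maxpool_bw(cache$idx, dy, as.integer(cache$xdim))

upsample2_fw <- function(x) {
  d <- dim(x)
  y <- x[, , rep(seq_len(d[3L]), each = 2L), rep(seq_len(d[4L]), each = 2L),
         drop = FALSE]
  list(y = y, cache = d)
}
upsample2_bw <- function(cache, dy) {
  oh <- c(TRUE, FALSE); eh <- c(FALSE, TRUE)
  dy[, , oh, oh, drop = FALSE] + dy[, , eh, oh, drop = FALSE] +
    dy[, , oh, eh, drop = FALSE] + dy[, , eh, eh, drop = FALSE]
}

# mean over the width axis: (N,C,H,W) -> (N,C,H,1)
pool_w_fw <- function(x) {
  d <- dim(x)
  y <- rowMeans(matrix(x, nrow = prod(d[1:3]), ncol = d[4L]))
  dim(y) <- c(d[1:3], 1L)
  list(y = y, cache = d)
}
pool_w_bw <- function(cache, dy) {
  d <- cache
  array(rep(as.vector(dy), times = d[4L]) / d[4L], d)
}

# mean over the height axis: (N,C,H,W) -> (N,C,1,W)
pool_h_fw <- function(x) {
  d <- dim(x)
  y <- colMeans(aperm(x, c(3L, 1L, 2L, 4L)))   # -> (N, C, W)
  dim(y) <- c(d[1L], d[2L], 1L, d[4L])
  list(y = y, cache = d)
}
pool_h_bw <- function(cache, dy) {
  d <- cache
  g <- as.vector(dy) / d[3L]                    # length N*C*W
  dim(g) <- c(d[1L], d[2L], d[4L])
  out <- aperm(array(rep(as.vector(g), each = d[3L]),
                     c(d[3L], d[1L], d[2L], d[4L])), c(2L, 3L, 1L, 4L))
  out
}

# global average pool: (N,C,H,W) -> (N,C,1,1)
gap_fw <- function(x) {
  d <- dim(x)
  y <- rowMeans(matrix(x, nrow = d[1L] * d[2L], ncol = d[3L] * d[4L]))
  dim(y) <- c(d[1L], d[2L], 1L, 1L)
  list(y = y, cache = d)
}
gap_bw <- function(cache, dy) {
  d <- cache
  array(rep(as.vector(dy), times = d[3L] * d[4L]) / (d[3L] * d[4L]), d)
}

concat_ch <- function(xs) {
  d1 <- dim(xs[[1L]])
  cs <- vapply(xs, nchan, integer(1L))
  y <- array(0, c(d1[1L], sum(cs), d1[3L], d1[4L]))
  at <- 0L
  for (x in xs) {
    cx <- nchan(x)
    y[, at + seq_len(cx), , ] <- x
    at <- at + cx
  }
  list(y = y, cs = cs)
}
split_ch <- function(dy, cs) {
  out <- vector("list", length(cs))
  at <- 0L
  for (i in seq_along(cs)) {
    out[[i]] <- dy[, at + seq_len(cs[i]), , , drop = FALSE]
    at <- at + cs[i]
  }
  out
}
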