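# Layer objects -----------------------------------------------------------
#
# A layer is an environment holding `params` (named list of numeric arrays),
# `grads` (accumulated, same names), `buffers` (non-learnable state such as
# BatchNorm running moments), and `children` (sub-layers). Forward passes in
# training mode push a cache onto `cache_stack`; backward pops it, so shared
# layers (the SSLDH stacks are applied once per pyramid level) unwind in
# exact LIFO order.

new_layer <- function(.kind, ...) {
  e <- new.env(parent = emptyenv())
  e$kind <- .kind
  e$params <- list()
  e$grads <- list()
  e$buffers <- list()
  e$children <- list()
  e$cache_stack <- list()
  extra <- list(...)
  for (nm in names(extra)) assign(nm, extra[[nm]], envir = e)
  class(e) <- c(paste0("bcsy_", .kind), "bcsy_layer")
  e
}

push_cache <- function(l, cache) {
  l$cache_stack[[length(l$cache_stack) + 1L]] <- cache
  invisible(NULL)
}
pop_cache <- function(l) {
  n <- length(l$cache_stack)
  if (n == 0L) stop("backward called without a matching forward on ", l$kind)
  cache <- l$cache_stack[[n]]
  l$cache_stack[[n]] <- NULL
  cache
}

# engine-wide mode switches: freeze_bn makes training-mode forwards use the
# stored running statistics (gradients still flow), so a student whose
# weights copy the teacher reproduces the teacher's eval-mode features
# exactly during distillation.
.engine <- new.env(parent = emptyenv())
.engine$freeze_bn <- FALSE
.engine$bn_calibrate <- FALSE

acc_grad <- function(l, name, g) {
  cur <- l$grads[[name]]
  l$grads[[name]] <- if (is.null(cur)) g else cur + g
  invisible(NULL)
}

# He-style init; callers control the RNG seed.
init_w <- function(cout, cing, k) {
  n <- cout * cing * k * k
  array(stats::rnorm(n, sd = sqrt(2 / (cing * k * k))), c(cout, cing, k, k))
}

# Universal convolution unit: conv -> optional BatchNorm/GroupNorm -> act.
conv_unit <- function(cin, cout, k = 1L, stride = 1L, groups = 1L,
                      norm = c("bn", "gn", "none"), act = "silu",
                      gn_groups = 1L, bias_init = 0) {
  norm <- match.arg(norm)
  l <- new_layer("conv_unit", cin = as.integer(cin), cout = as.integer(cout),
                 k = as.integer(k), stride = as.integer(stride),
                 groups = as.integer(groups), norm = norm, act = act,
                 gn_groups = as.integer(gn_groups))
  l$params$w <- init_w(cout, cin %/% groups, k)
  if (norm == "none") {
    l$params$b <- rep(bias_init, cout)
  } else {
    l$params$gamma <- rep(1, cout)
    l$params$beta <- rep(0, cout)
    if (norm == "bn") {
      l$buffers$rm <- rep(0, cout)
      l$buffers$rv <- rep(1, cout)
    }
  }
  l
}

fwd_conv_unit <- function(l, x, training) {
  cv <- conv_fw(x, l$params$w, l$params[["b"]], l$stride, NULL, l$groups)
  y <- cv$y
  nc <- NULL
  if (l$norm == "bn") {
    use_batch <- training && !isTRUE(.engine$freeze_bn)
    calib <- isTRUE(.engine$bn_calibrate)
    nr <- bn_fw(y, l$params$gamma, l$params$beta, l$buffers$rm, l$buffers$rv,
                use_batch, momentum = if (calib) 1 else 0.03,
                unbias = !calib)
    if (use_batch) { l$buffers$rm <- nr$rm; l$buffers$rv <- nr$rv }
    y <- nr$y; nc <- nr$cache
  } else if (l$norm == "gn") {
    nr <- gn_fw(y, l$params$gamma, l$params$beta, l$gn_groups)
    y <- nr$y; nc <- nr$cache
  }
  ac <- act_fw(y, l$act)
  if (training) push_cache(l, list(conv = cv$cache, norm = nc, act = ac$cache))
  ac$y
}

bwd_conv_unit <- function(l, dy) {
  cache <- pop_cache(l)
  dy <- act_bw(cache$act, dy, l$act)
  if (l$norm == "bn") {
    r <- bn_bw(cache$norm, dy)
    acc_grad(l, "gamma", r$dgamma); acc_grad(l, "beta", r$dbeta)
    dy <- r$dx
  } else if (l$norm == "gn") {
    r <- gn_bw(cache$norm, dy)
    acc_grad(l, "gamma", r$dgamma); acc_grad(l, "beta", r$dbeta)
    dy <- r$dx
  }
  r <- conv_bw(cache$conv, dy)
  acc_grad(l, "w", r$dw)
  if (!is.null(r$db)) acc_grad(l, "b", r$db)
  r$dx
}

# Standard residual bottleneck (two 3x3 convs) used by the baseline C2f.
bottleneck_layer <- function(c, shortcut = TRUE) {
  l <- new_layer("bottleneck", c = c, shortcut = shortcut)
  l$children$cv1 <- conv_unit(c, c, 3L)
  l$children$cv2 <- conv_unit(c, c, 3L)
  l
}
fwd_bottleneck <- function(l, x, training) {
  y <- ly_fwd(l$children$cv2, ly_fwd(l$children$cv1, x, training), training)
  if (l$shortcut) y + x else y
}
bwd_bottleneck <- function(l, dy) {
  dx <- ly_bwd(l$children$cv1, ly_bwd(l$children$cv2, dy))
  if (l$shortcut) dx + dy else dx
}

# Star block: depthwise conv, two parallel pointwise expansions fused by an
# element-wise product (activation on branch 1 only), pointwise projection,
# second depthwise conv, residual.
star_block_layer <- function(c, expand_ratio = 3, dw_kernel = 5L,
                             act = "silu", residual = TRUE) {
  if (dw_kernel %% 2L == 0L) stop("star block dw_kernel must be odd")
  if (expand_ratio <= 0) stop("star block expand_ratio must be positive")
  ce <- as.integer(round(expand_ratio * c))
  l <- new_layer("star_block", c = c, ce = ce, act = act, residual = residual,
                 dw_kernel = as.integer(dw_kernel))
  l$children$dw1 <- conv_unit(c, c, dw_kernel, groups = c, norm = "bn", act = "none")
  l$children$f1 <- conv_unit(c, ce, 1L, norm = "none", act = "none")
  l$children$f2 <- conv_unit(c, ce, 1L, norm = "none", act = "none")
  l$children$g <- conv_unit(ce, c, 1L, norm = "bn", act = "none")
  l$children$dw2 <- conv_unit(c, c, dw_kernel, groups = c, norm = "none", act = "none")
  l
}
fwd_star_block <- function(l, x, training) {
  t <- ly_fwd(l$children$dw1, x, training)
  a <- ly_fwd(l$children$f1, t, training)
  b <- ly_fwd(l$children$f2, t, training)
  aa <- act_fw(a, l$act)
  m <- aa$y * b
  u <- ly_fwd(l$children$dw2, ly_fwd(l$children$g, m, training), training)
  if (training) push_cache(l, list(act = aa$cache, act_y = aa$y, b = b))
  if (l$residual) x + u else u
}
bwd_star_block <- function(l, dy) {
  cache <- pop_cache(l)
  dm <- ly_bwd(l$children$g, ly_bwd(l$children$dw2, dy))
  da <- act_bw(cache$act, dm * cache$b, l$act)
  db <- dm * cache$act_y
  dt <- ly_bwd(l$children$f1, da) + ly_bwd(l$children$f2, db)
  dx <- ly_bwd(l$children$dw1, dt)
  if (l$residual) dx + dy else dx
}

# Grouped reshape helpers for EMA: (N, C, H, W) <-> (N*G, C/G, H, W)
group_fold <- function(x, G) {
  d <- dim(x); N <- d[1L]; C <- d[2L]; Cg <- C %/% G
  dim(x) <- c(N, Cg, G, d[3L], d[4L])
  x <- aperm(x, c(1L, 3L, 2L, 4L, 5L))
  dim(x) <- c(N * G, Cg, d[3L], d[4L])
  x
}
group_unfold <- function(x, N, G) {
  d <- dim(x); Cg <- d[2L]
  dim(x) <- c(N, G, Cg, d[3L], d[4L])
  x <- aperm(x, c(1L, 3L, 2L, 4L, 5L))
  dim(x) <- c(N, G * Cg, d[3L], d[4L])
  x
}

softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1L, max))
  e / rowSums(e)
}

# Efficient multi-scale attention. `variant = "paper_eqs"` implements only
# the directional-pooling gate z = sigma(W1 [z_H (+) z_W]); "full_cited" adds
# the 3x3 branch and the cross-spatial interaction of the cited module.
ema_layer <- function(c, groups = 4L, variant = c("full_cited", "paper_eqs")) {
  variant <- match.arg(variant)
  G <- as.integer(groups)
  if (G < 1L || c %% G != 0L)
    stop("EMA: ", c, " channels not divisible into ", G, " groups")
  cg <- c %/% G
  l <- new_layer("ema", c = c, G = G, cg = cg, variant = variant)
  l$children$conv1 <- conv_unit(cg, cg, 1L, norm = "none", act = "none")
  if (variant == "full_cited") {
    l$children$conv3 <- conv_unit(cg, cg, 3L, norm = "none", act = "none")
    l$params$gamma <- rep(1, cg)
    l$params$beta <- rep(0, cg)
  }
  l
}

fwd_ema <- function(l, x, training) {
  d <- dim(x); N <- d[1L]; H <- d[3L]; W <- d[4L]
  G <- l$G; cg <- l$cg
  xg <- group_fold(x, G)
  pw <- pool_w_fw(xg)                       # z^H: mean over width, (NG,cg,H,1)
  ph <- pool_h_fw(xg)                       # z^W: mean over height, (NG,cg,1,W)
  zwt <- aperm(ph$y, c(1L, 2L, 4L, 3L))     # -> (NG,cg,W,1)
  cc <- concat_3rd(pw$y, zwt)               # (NG,cg,H+W,1)
  cv <- conv_fw(cc$y, l$children$conv1$params$w, l$children$conv1$params$b)
  gh_raw <- cv$y[, , seq_len(H), , drop = FALSE]
  gw_raw <- cv$y[, , H + seq_len(W), , drop = FALSE]
  sh <- sigmoid_fw(gh_raw)
  sw <- sigmoid_fw(gw_raw)
  ghb <- as.vector(sh$y)                    # recycles over the W axis
  gwb <- aperm(sw$y, c(1L, 2L, 4L, 3L))[, , rep(1L, H), , drop = FALSE]
  xm <- xg * ghb * gwb
  if (l$variant == "paper_eqs") {
    y <- group_unfold(xm, N, G)
    if (training)
      push_cache(l, list(N = N, H = H, W = W, pw = pw$cache, ph = ph$cache,
                         conv = cv$cache, sh = sh$cache, sw = sw$cache,
                         xg = xg, ghb = ghb, gwb = gwb))
    return(y)
  }
  gr <- gn_fw(xm, l$params$gamma, l$params$beta, groups = cg)
  x1 <- gr$y
  c3 <- conv_fw(xg, l$children$conv3$params$w, l$children$conv3$params$b)
  x2 <- c3$y
  g1 <- gap_fw(x1); g2 <- gap_fw(x2)
  s1 <- softmax_rows(matrix(g1$y, N * G, cg))
  s2 <- softmax_rows(matrix(g2$y, N * G, cg))
  NG <- N * G; S <- H * W
  m1 <- matrix(x2, NG, cg * S); m2 <- matrix(x1, NG, cg * S)
  wsum <- matrix(0, NG, S)
  for (i in seq_len(NG)) {
    wsum[i, ] <- s1[i, ] %*% matrix(m1[i, ], cg, S) +
                 s2[i, ] %*% matrix(m2[i, ], cg, S)
  }
  prof_add(2 * 2 * cg * S * NG)
  sg <- 1 / (1 + exp(-wsum))                  # (NG, S)
  sgb <- array(0, c(NG, cg, S))               # broadcast over channels
  for (ci in seq_len(cg)) sgb[, ci, ] <- sg
  dim(sgb) <- c(NG, cg, H, W)
  y <- group_unfold(xg * sgb, N, G)
  if (training)
    push_cache(l, list(N = N, H = H, W = W, pw = pw$cache, ph = ph$cache,
                       conv = cv$cache, sh = sh$cache, sw = sw$cache,
                       xg = xg, ghb = ghb, gwb = gwb, gn = gr$cache,
                       c3 = c3$cache, x1 = x1, x2 = x2, s1 = s1, s2 = s2,
                       g1 = g1$cache, g2 = g2$cache, sg = sg, sgb = sgb))
  y
}

bwd_ema <- function(l, dy) {
  cache <- pop_cache(l)
  N <- cache$N; H <- cache$H; W <- cache$W
  G <- l$G; cg <- l$cg; NG <- N * G; S <- H * W
  dyg <- group_fold(dy, G)
  if (l$variant == "paper_eqs") {
    dxm <- dyg
    dxg <- dxm * cache$ghb * cache$gwb
    dparts <- ema_gate_bw(l, cache, dxm, dxg, NG, cg, H, W)
    return(group_unfold(dparts, N, G))
  }
  xg <- cache$xg; sgb <- cache$sgb; sg <- cache$sg
  dxg <- dyg * sgb
  dsg <- matrix(0, NG, S)
  dy_x <- dyg * xg
  dim(dy_x) <- c(NG, cg, S)
  for (ci in seq_len(cg)) dsg <- dsg + dy_x[, ci, ]
  dwsum <- dsg * sg * (1 - sg)
  ds1 <- matrix(0, NG, cg); ds2 <- matrix(0, NG, cg)
  dx1 <- array(0, c(NG, cg, H, W)); dx2 <- array(0, c(NG, cg, H, W))
  m1 <- matrix(cache$x2, NG, cg * S); m2 <- matrix(cache$x1, NG, cg * S)
  for (i in seq_len(NG)) {
    X2 <- matrix(m1[i, ], cg, S); X1 <- matrix(m2[i, ], cg, S)
    dv <- dwsum[i, ]
    ds1[i, ] <- X2 %*% dv
    ds2[i, ] <- X1 %*% dv
    dx2[i, , , ] <- array(outer(cache$s1[i, ], dv), c(cg, H, W))
    dx1[i, , , ] <- dx1[i, , , ] + array(outer(cache$s2[i, ], dv), c(cg, H, W))
  }
  smax_bw <- function(s, ds) s * (ds - rowSums(ds * s))
  dg1 <- smax_bw(cache$s1, ds1); dg2 <- smax_bw(cache$s2, ds2)
  dx1 <- dx1 + gap_bw(cache$g1, array(dg1, c(NG, cg, 1L, 1L)))
  dx2 <- dx2 + gap_bw(cache$g2, array(dg2, c(NG, cg, 1L, 1L)))
  r3 <- conv_bw(cache$c3, dx2)
  acc_grad(l$children$conv3, "w", r3$dw); acc_grad(l$children$conv3, "b", r3$db)
  dxg <- dxg + r3$dx
  rg <- gn_bw(cache$gn, dx1)
  acc_grad(l, "gamma", rg$dgamma); acc_grad(l, "beta", rg$dbeta)
  dxm <- rg$dx
  dxg <- dxg + dxm * cache$ghb * cache$gwb
  dxg <- ema_gate_bw(l, cache, dxm, dxg, NG, cg, H, W)
  group_unfold(dxg, N, G)
}

# shared tail of the EMA backward: gradients through the directional gates,
# the 1x1 conv and the two pooling passes. `dxm` is the gradient on the gated
# map, `dxg` the gradient already accumulated on the grouped input.
ema_gate_bw <- function(l, cache, dxm, dxg, NG, cg, H, W) {
  xg <- cache$xg
  dghb_full <- dxm * xg * cache$gwb            # reduce over W -> (NG,cg,H,1)
  dgh <- rowSums(matrix(dghb_full, NG * cg * H, W))
  dim(dgh) <- c(NG, cg, H, 1L)
  dgwb_full <- dxm * xg * cache$ghb            # reduce over H -> (NG,cg,1,W)
  tmp <- colSums(aperm(dgwb_full, c(3L, 1L, 2L, 4L)))
  dim(tmp) <- c(NG, cg, 1L, W)
  dgw <- aperm(tmp, c(1L, 2L, 4L, 3L))         # -> (NG,cg,W,1)
  dgh_raw <- sigmoid_bw(cache$sh, dgh)
  dgw_raw <- sigmoid_bw(cache$sw, dgw)
  dcc <- array(0, c(NG, cg, H + W, 1L))
  dcc[, , seq_len(H), ] <- dgh_raw
  dcc[, , H + seq_len(W), ] <- dgw_raw
  r1 <- conv_bw(cache$conv, dcc)
  acc_grad(l$children$conv1, "w", r1$dw); acc_grad(l$children$conv1, "b", r1$db)
  dzh <- r1$dx[, , seq_len(H), , drop = FALSE]
  dzwt <- r1$dx[, , H + seq_len(W), , drop = FALSE]
  dzw <- aperm(dzwt, c(1L, 2L, 4L, 3L))
  dxg + pool_w_bw(cache$pw, dzh) + pool_h_bw(cache$ph, dzw)
}

concat_3rd <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1L], da[2L], da[3L] + db[3L], da[4L]))
  y[, , seq_len(da[3L]), ] <- a
  y[, , da[3L] + seq_len(db[3L]), ] <- b
  list(y = y)
}

# C2f skeleton: split -> n stacked inner blocks with partial concatenation
# -> fuse conv; optional EMA applied once after the fuse conv.
c2f_layer <- function(cin, cout, n = 1L, shortcut = FALSE,
                      block = c("c2f_baseline", "c2f_star", "c2f_star_ema"),
                      opts = list()) {
  block <- match.arg(block)
  if (n < 1L) stop("C2f requires n_blocks >= 1")
  c <- cout %/% 2L
  l <- new_layer("c2f", cin = cin, cout = cout, c = c, n = as.integer(n),
                 block = block)
  l$children$cv1 <- conv_unit(cin, 2L * c, 1L)
  for (i in seq_len(n)) {
    l$children[[paste0("m", i)]] <-
      if (block == "c2f_baseline") bottleneck_layer(c, shortcut)
      else star_block_layer(c,
                            expand_ratio = opts$star_expand %||% 3,
                            dw_kernel = opts$dw_kernel %||% 5L,
                            act = opts$branch_act %||% "silu")
  }
  l$children$cv2 <- conv_unit((2L + n) * c, cout, 1L)
  if (block == "c2f_star_ema")
    l$children$ema <- ema_layer(cout, groups = opts$ema_groups %||% 4L,
                                variant = opts$ema_variant %||% "full_cited")
  l
}

fwd_c2f <- function(l, x, training) {
  v <- ly_fwd(l$children$cv1, x, training)
  c <- l$c
  parts <- list(v[, seq_len(c), , , drop = FALSE],
                v[, c + seq_len(c), , , drop = FALSE])
  cur <- parts[[2L]]
  for (i in seq_len(l$n)) {
    cur <- ly_fwd(l$children[[paste0("m", i)]], cur, training)
    parts[[i + 2L]] <- cur
  }
  y <- ly_fwd(l$children$cv2, concat_ch(parts)$y, training)
  if (!is.null(l$children$ema)) y <- ly_fwd(l$children$ema, y, training)
  y
}

bwd_c2f <- function(l, dy) {
  if (!is.null(l$children$ema)) dy <- ly_bwd(l$children$ema, dy)
  dcat <- ly_bwd(l$children$cv2, dy)
  c <- l$c; n <- l$n
  dparts <- split_ch(dcat, rep(c, n + 2L))
  dcur <- dparts[[n + 2L]]
  for (i in rev(seq_len(n))) {
    din <- ly_bwd(l$children[[paste0("m", i)]], dcur)
    dcur <- din + dparts[[i + 1L]]
  }
  dv <- array(0, c(dim(dparts[[1L]])[1L], 2L * c, dim(dparts[[1L]])[3:4]))
  dv[, seq_len(c), , ] <- dparts[[1L]]
  dv[, c + seq_len(c), , ] <- dcur
  ly_bwd(l$children$cv1, dv)
}

sppf_layer <- function(cin, cout, k = 5L) {
  ch <- cin %/% 2L
  l <- new_layer("sppf", cin = cin, cout = cout, ch = ch, k = as.integer(k))
  l$children$cv1 <- conv_unit(cin, ch, 1L)
  l$children$cv2 <- conv_unit(4L * ch, cout, 1L)
  l
}
fwd_sppf <- function(l, x, training) {
  p0 <- ly_fwd(l$children$cv1, x, training)
  m1 <- maxpool_fw(p0, l$k); m2 <- maxpool_fw(m1$y, l$k); m3 <- maxpool_fw(m2$y, l$k)
  if (training) push_cache(l, list(m1 = m1$cache, m2 = m2$cache, m3 = m3$cache))
  ly_fwd(l$children$cv2, concat_ch(list(p0, m1$y, m2$y, m3$y))$y, training)
}
bwd_sppf <- function(l, dy) {
  cache <- pop_cache(l)
  dcat <- ly_bwd(l$children$cv2, dy)
  ch <- l$ch
  ds <- split_ch(dcat, rep(ch, 4L))
  dm2 <- maxpool_bw(cache$m3, ds[[4L]]) + ds[[3L]]
  dm1 <- maxpool_bw(cache$m2, dm2) + ds[[2L]]
  dp0 <- maxpool_bw(cache$m1, dm1) + ds[[1L]]
  ly_bwd(l$children$cv1, dp0)
}

upsample_layer <- function() new_layer("upsample")
fwd_upsample <- function(l, x, training) {
  r <- upsample2_fw(x)
  if (training) push_cache(l, r$cache)
  r$y
}
bwd_upsample <- function(l, dy) upsample2_bw(pop_cache(l), dy)

# Baseline decoupled detection head (separate per-level reg/cls stacks).
detect_base_layer <- function(chs, nc = 5L, reg_max = 16L) {
  c2 <- max(16L, chs[1L] %/% 4L, 4L * reg_max)
  c3 <- max(chs[1L], min(nc, 100L))
  l <- new_layer("detect_base", chs = chs, nc = as.integer(nc),
                 reg_max = as.integer(reg_max), c2 = c2, c3 = c3)
  for (i in 1:3) {
    l$children[[paste0("r1_", i)]] <- conv_unit(chs[i], c2, 3L)
    l$children[[paste0("r2_", i)]] <- conv_unit(c2, c2, 3L)
    l$children[[paste0("r3_", i)]] <- conv_unit(c2, 4L * reg_max, 1L,
                                                norm = "none", act = "none",
                                                bias_init = 1)
    l$children[[paste0("c1_", i)]] <- conv_unit(chs[i], c3, 3L)
    l$children[[paste0("c2_", i)]] <- conv_unit(c3, c3, 3L)
    l$children[[paste0("c3_", i)]] <- conv_unit(c3, nc, 1L,
                                                norm = "none", act = "none",
                                                bias_init = -4.6)
  }
  l$buffers$dfl_bins <- as.numeric(0:(reg_max - 1L))
  l
}
fwd_detect_base <- function(l, xs, training) {
  reg <- vector("list", 3L); cls <- vector("list", 3L)
  for (i in 1:3) {
    reg[[i]] <- ly_fwd(l$children[[paste0("r3_", i)]],
                ly_fwd(l$children[[paste0("r2_", i)]],
                ly_fwd(l$children[[paste0("r1_", i)]], xs[[i]], training),
                training), training)
    cls[[i]] <- ly_fwd(l$children[[paste0("c3_", i)]],
                ly_fwd(l$children[[paste0("c2_", i)]],
                ly_fwd(l$children[[paste0("c1_", i)]], xs[[i]], training),
                training), training)
  }
  list(reg = reg, cls = cls)
}
bwd_detect_base <- function(l, dout) {
  dxs <- vector("list", 3L)
  for (i in 3:1) {
    dc <- ly_bwd(l$children[[paste0("c1_", i)]],
          ly_bwd(l$children[[paste0("c2_", i)]],
          ly_bwd(l$children[[paste0("c3_", i)]], dout$cls[[i]])))
    dr <- ly_bwd(l$children[[paste0("r1_", i)]],
          ly_bwd(l$children[[paste0("r2_", i)]],
          ly_bwd(l$children[[paste0("r3_", i)]], dout$reg[[i]])))
    dxs[[i]] <- dc + dr
  }
  dxs
}

largest_divisor_leq <- function(n, cap) {
  for (d in cap:1L) if (n %% d == 0L) return(d)
  1L
}

# SSLDH: per-level GroupNorm 1x1 adapters, shared GroupNorm 3x3 stacks, a
# star-style multiplicative FC interaction, shared output convs, per-level
# learnable scales on the regression branch.
ssldh_layer <- function(chs, nc = 5L, reg_max = 16L, hidden = 56L,
                        gn_groups = NULL, fc_expand = 1.5,
                        shared_outputs = TRUE) {
  hidden <- as.integer(hidden)
  if (is.null(gn_groups)) gn_groups <- largest_divisor_leq(hidden, 16L)
  hh <- as.integer(round(fc_expand * hidden))
  l <- new_layer("ssldh", chs = chs, nc = as.integer(nc),
                 reg_max = as.integer(reg_max), hidden = hidden, hh = hh,
                 gn_groups = as.integer(gn_groups),
                 shared_outputs = isTRUE(shared_outputs))
  for (i in 1:3)
    l$children[[paste0("ad_", i)]] <-
      conv_unit(chs[i], hidden, 1L, norm = "gn", gn_groups = gn_groups)
  l$children$s1 <- conv_unit(hidden, hidden, 3L, norm = "gn", gn_groups = gn_groups)
  l$children$f1 <- conv_unit(hidden, hh, 1L, norm = "none", act = "none")
  l$children$f2 <- conv_unit(hidden, hh, 1L, norm = "none", act = "none")
  l$children$s2 <- conv_unit(hh, hidden, 3L, norm = "gn", gn_groups = gn_groups)
  out_names <- if (l$shared_outputs) list(reg = "", cls = "")
               else list(reg = 1:3, cls = 1:3)
  for (sfx in out_names$reg)
    l$children[[paste0("reg", sfx)]] <-
      conv_unit(hidden, 4L * reg_max, 1L, norm = "none", act = "none",
                bias_init = 1)
  for (sfx in out_names$cls)
    l$children[[paste0("cls", sfx)]] <-
      conv_unit(hidden, nc, 1L, norm = "none", act = "none",
                bias_init = -4.6)
  l$params$scales <- rep(1, 3L)
  l$buffers$dfl_bins <- as.numeric(0:(reg_max - 1L))
  l
}
ssldh_out <- function(l, kind, i) {
  l$children[[if (l$shared_outputs) kind else paste0(kind, i)]]
}
fwd_ssldh <- function(l, xs, training) {
  reg <- vector("list", 3L); cls <- vector("list", 3L)
  caches <- vector("list", 3L)
  for (i in 1:3) {
    t <- ly_fwd(l$children[[paste0("ad_", i)]], xs[[i]], training)
    t <- ly_fwd(l$children$s1, t, training)
    a <- ly_fwd(l$children$f1, t, training)
    b <- ly_fwd(l$children$f2, t, training)
    aa <- silu_fw(a)
    m <- aa$y * b
    u <- ly_fwd(l$children$s2, m, training)
    rr <- ly_fwd(ssldh_out(l, "reg", i), u, training)
    reg[[i]] <- rr * l$params$scales[i]
    cls[[i]] <- ly_fwd(ssldh_out(l, "cls", i), u, training)
    caches[[i]] <- list(act = aa$cache, act_y = aa$y, b = b, reg_raw = rr)
  }
  if (training) push_cache(l, caches)
  list(reg = reg, cls = cls)
}
bwd_ssldh <- function(l, dout) {
  caches <- pop_cache(l)
  dxs <- vector("list", 3L)
  dscales <- numeric(3L)
  for (i in 3:1) {            # strict reverse order for the shared stacks
    ci <- caches[[i]]
    dscales[i] <- sum(dout$reg[[i]] * ci$reg_raw)
    drr <- dout$reg[[i]] * l$params$scales[i]
    du <- ly_bwd(ssldh_out(l, "reg", i), drr) +
      ly_bwd(ssldh_out(l, "cls", i), dout$cls[[i]])
    dm <- ly_bwd(l$children$s2, du)
    da <- silu_bw(ci$act, dm * ci$b)
    db <- dm * ci$act_y
    dt <- ly_bwd(l$children$f1, da) + ly_bwd(l$children$f2, db)
    dt <- ly_bwd(l$children$s1, dt)
    dxs[[i]] <- ly_bwd(l$children[[paste0("ad_", i)]], dt)
  }
  acc_grad(l, "scales", dscales)
  dxs
}

# dispatch ---------------------------------------------------------------

ly_fwd <- function(l, x, training = FALSE) {
  switch(l$kind,
         conv_unit = fwd_conv_unit(l, x, training),
         bottleneck = fwd_bottleneck(l, x, training),
         star_block = fwd_star_block(l, x, training),
         ema = fwd_ema(l, x, training),
         c2f = fwd_c2f(l, x, training),
         sppf = fwd_sppf(l, x, training),
         upsample = fwd_upsample(l, x, training),
         detect_base = fwd_detect_base(l, x, training),
         ssldh = fwd_ssldh(l, x, training),
         stop("unknown layer kind: ", l$kind))
}

ly_bwd <- function(l, dy) {
  switch(l$kind,
         conv_unit = bwd_conv_unit(l, dy),
         bottleneck = bwd_bottleneck(l, dy),
         star_block = bwd_star_block(l, dy),
         ema = bwd_ema(l, dy),
         c2f = bwd_c2f(l, dy),
         sppf = bwd_sppf(l, dy),
         upsample = bwd_upsample(l, dy),
         detect_base = bwd_detect_base(l, dy),
         ssldh = bwd_ssldh(l, dy),
         stop("unknown layer kind: ", l$kind))
}

# recursive walkers -------------------------------------------------------

walk_layers <- function(l, fn, path = "") {
  fn(l, path)
  for (nm in names(l$children)) walk_layers(l$children[[nm]], fn,
                                            paste0(path, ".", nm))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
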