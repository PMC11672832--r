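# star operation, star block, EMA attention, C2f-Star-EMA composite

test_that("star product is the elementwise product with shape checking", {
  b <- rand_fm(3, 4, 5, seed = 1)
  expect_equal(star_product(array(1, dim(b)), b), b)
  expect_equal(star_product(array(0, dim(b)), b), array(0, dim(b)))
  expect_error(star_product(matrix(1, 2, 3), matrix(1, 3, 2)),
               "shape mismatch")
  # commutativity and bilinearity
  a <- rand_fm(3, 4, 5, seed = 2)
  expect_identical(star_product(a, b), star_product(b, a))
  expect_equal(star_product(2.5 * a, b), 2.5 * star_product(a, b))
  expect_equal(star_product(a + b, b), star_product(a, b) + star_product(b, b))
})

test_that("star of two linear maps equals the double-sum monomial expansion", {
  # brute-force oracle: (w1'x)(w2'x) = sum_i sum_j w1_i w2_j x_i x_j
  set.seed(42)
  for (rep in seq_len(25)) {
    d <- sample(1:8, 1)
    w1 <- rnorm(d + 1); w2 <- rnorm(d + 1); x <- rnorm(d + 1)
    lhs <- star_product(sum(w1 * x), sum(w2 * x))
    rhs <- 0
    for (i in seq_len(d + 1))
      for (j in seq_len(d + 1))
        rhs <- rhs + w1[i] * w2[j] * x[i] * x[j]
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("implicit monomial count matches explicit enumeration", {
  expect_identical(implicit_monomial_count(0), 1L)
  # enumeration oracle: distinct unordered pairs (i, j), i <= j, over d+1 slots
  enum <- function(d) {
    n <- 0L
    for (i in seq_len(d + 1)) for (j in i:(d + 1)) n <- n + 1L
    n
  }
  expect_identical(implicit_monomial_count(1), enum(1))  # {x1^2, x1*1, 1^2}
  expect_identical(implicit_monomial_count(3), enum(3))
  expect_identical(implicit_monomial_count(3), 10L)
  for (d in c(2, 5, 9)) expect_identical(implicit_monomial_count(d), enum(d))
  expect_error(implicit_monomial_count(-1), "non-negative")
})

test_that("star block: residual identity, shape preservation, channel check", {
  set.seed(3)
  p <- star_block_params(6)
  x <- rand_fm(6, 5, 7, seed = 4)
  # zero projection -> inner path contributes exactly nothing
  p$children$g$params$w[] <- 0
  p$children$g$params$beta[] <- 0
  p$children$dw2$params$b[] <- 0
  expect_equal(star_block_forward(x, p), x)
  # generic weights preserve shape for any odd kernel
  for (k in c(3, 5, 7)) {
    set.seed(10 + k)
    pk <- star_block_params(6, dw_kernel = k)
    expect_identical(dim(star_block_forward(x, pk)), dim(x))
  }
  expect_error(star_block_params(6, dw_kernel = 4), "odd")
  expect_error(star_block_forward(rand_fm(5, 5, 7), p), "channel mismatch")
})

test_that("star block single-pixel output equals the scalar-path composition", {
  set.seed(9)
  C <- 4
  p <- star_block_params(C, expand_ratio = 2, dw_kernel = 5)
  x <- rand_fm(C, 1, 1, seed = 10)
  # by hand: only the center tap of each depthwise kernel sees a 1x1 input
  xv <- as.vector(x)
  dwc <- function(l, v) {                     # depthwise conv at 1x1 spatial
    k <- dim(l$params$w)[3L]
    ctr <- (k + 1) / 2
    out <- vapply(seq_len(C), function(c) l$params$w[c, 1, ctr, ctr] * v[c],
                  numeric(1))
    if (!is.null(l$params[["b"]])) out <- out + l$params[["b"]]
    if (l$norm == "bn")
      out <- l$params$gamma / sqrt(1 + 1e-5) * out + l$params$beta
    out
  }
  t <- dwc(p$children$dw1, xv)
  f1 <- matrix(p$children$f1$params$w, ncol = C) %*% t + p$children$f1$params$b
  f2 <- matrix(p$children$f2$params$w, ncol = C) %*% t + p$children$f2$params$b
  m <- ref_silu(f1) * f2
  g <- matrix(p$children$g$params$w, ncol = length(m)) %*% m
  g <- p$children$g$params$gamma / sqrt(1 + 1e-5) * as.vector(g) +
    p$children$g$params$beta
  u <- dwc(p$children$dw2, g)
  expect_equal(as.vector(star_block_forward(x, p)), xv + u, tolerance = 1e-10)
})

test_that("directional pooling matches hand-computed averages", {
  # x with rows (1,3) and (5,7): mean over width per row = (2, 6),
  # mean over height per column = (3, 5)
  x <- array(0, c(1, 2, 2))
  x[1, 1, ] <- c(1, 3); x[1, 2, ] <- c(5, 7)
  dp <- directional_pool(x)
  expect_equal(as.vector(dp$zH), c(2, 6))
  expect_equal(as.vector(dp$zW), c(3, 5))
})

test_that("EMA gate: constant input gives a spatially uniform output", {
  set.seed(5)
  p <- ema_params(8, groups = 2, variant = "paper_eqs")
  x <- array(1.7, c(8, 6, 9))
  y <- ema_forward(x, p)
  expect_identical(dim(y), dim(x))
  for (c in 1:8) expect_lt(diff(range(y[c, , ])), 1e-12)
  # gates are sigmoids: the modulated output is strictly between 0 and x
  expect_true(all(y > 0 & y < 1.7))
})

test_that("paper_eqs EMA equals an independent step-by-step evaluation", {
  set.seed(6)
  G <- 2
  p <- ema_params(4, groups = G, variant = "paper_eqs")
  x <- rand_fm(4, 3, 5, seed = 8)
  # oracle: per group, pool H then W, concat H-first, shared 1x1, sigmoid,
  # multiplicative gates
  w1 <- p$children$conv1$params$w
  b1 <- p$children$conv1$params$b
  cg <- 2
  y_ref <- array(0, dim(x))
  for (g in seq_len(G)) {
    ch <- (g - 1) * cg + seq_len(cg)
    xg <- x[ch, , , drop = FALSE]
    zh <- apply(xg, c(1, 2), mean)            # cg x H
    zw <- apply(xg, c(1, 3), mean)            # cg x W
    cc <- cbind(zh, zw)                       # cg x (H + W), H first
    conv <- matrix(w1, cg, cg) %*% cc + b1
    gh <- ref_sigmoid(conv[, seq_len(3)])
    gw <- ref_sigmoid(conv[, 3 + seq_len(5)])
    for (ci in seq_len(cg))
      y_ref[ch[ci], , ] <- xg[ci, , ] * outer(gh[ci, ], gw[ci, ])
  }
  expect_equal(ema_forward(x, p), y_ref, tolerance = 1e-12)
})

test_that("EMA preserves shape across group counts and validates divisibility", {
  for (spec in list(c(8, 4, 6, 2), c(12, 3, 3, 4), c(6, 5, 2, 6))) {
    set.seed(spec[1])
    p <- ema_params(spec[1], groups = spec[4], variant = "full_cited")
    x <- rand_fm(spec[1], spec[2], spec[3], N = 2)
    y <- ema_forward(x, p)
    expect_identical(dim(y), dim(x))
    expect_true(all(is.finite(y)))
  }
  expect_error(ema_params(10, groups = 4), "divisible")
})

test_that("C2f-Star-EMA skeleton, identity inner block, and lightness", {
  set.seed(11)
  p <- c2f_star_ema_params(6, 8, n_blocks = 1,
                           opts = list(ema_groups = 2))
  x <- rand_fm(6, 4, 4, seed = 12)
  y <- c2f_star_ema_forward(x, 1, p)
  expect_identical(dim(y), c(8L, 4L, 4L))
  expect_error(c2f_star_ema_forward(x, 2, p), "does not match")
  expect_error(c2f_star_ema_params(6, 8, n_blocks = 0), "n_blocks")

  # with the inner star block silenced, the composite reduces to
  # fuse_conv(concat(y1, y2, y2)) followed by EMA — verified against an
  # independent composition using reference 1x1 algebra
  sb <- p$children$m1
  sb$children$g$params$w[] <- 0
  sb$children$g$params$beta[] <- 0
  sb$children$dw2$params$b[] <- 0
  v <- ref_bn_init(ref_conv1x1(x, p$children$cv1$params$w),
                   p$children$cv1$params$gamma, p$children$cv1$params$beta)
  v <- ref_silu(v)
  y1 <- v[1:4, , , drop = FALSE]; y2 <- v[5:8, , , drop = FALSE]
  cc <- array(0, c(12, 4, 4))
  cc[1:4, , ] <- y1; cc[5:8, , ] <- y2; cc[9:12, , ] <- y2
  fused <- ref_silu(ref_bn_init(ref_conv1x1(cc, p$children$cv2$params$w),
                                p$children$cv2$params$gamma,
                                p$children$cv2$params$beta))
  expect_equal(c2f_star_ema_forward(x, 1, p),
               ema_forward(fused, p$children$ema), tolerance = 1e-10)
})

test_that("star/EMA composite is lighter than the baseline C2f it replaces", {
  # backbone-stage widths of the n-scale model
  for (w in list(c(32, 32, 1), c(64, 64, 2), c(128, 128, 2), c(256, 256, 1))) {
    set.seed(w[1])
    base <- bcsyolo:::c2f_layer(w[1], w[2], w[3], TRUE, "c2f_baseline")
    star <- bcsyolo:::c2f_layer(w[1], w[2], w[3], TRUE, "c2f_star_ema",
                                opts = list())
    expect_lt(count_params(star), count_params(base))
  }
})

test_that("blocks are deterministic and finite on bounded input", {
  set.seed(13)
  p <- c2f_star_ema_params(8, 8, n_blocks = 2, opts = list(ema_groups = 4))
  x <- rand_fm(8, 6, 6, seed = 14)
  y1 <- c2f_star_ema_forward(x, 2, p)
  y2 <- c2f_star_ema_forward(x, 2, p)
  expect_identical(y1, y2)
  expect_true(all(is.finite(y1)))
})
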