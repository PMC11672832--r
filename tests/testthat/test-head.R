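# SSLDH head: GroupNorm conv, weight sharing, scales, box decoding

test_that("GroupNorm normalizes each group to zero mean / unit variance", {
  set.seed(21)
  x <- rand_fm(8, 5, 6, N = 3)
  r <- bcsyolo:::gn_fw(x, gamma = rep(1, 8), beta = rep(0, 8), groups = 4)
  y <- r$y
  dim(y) <- c(3, 2, 4, 30)          # N, C/G, G, S
  for (n in 1:3) for (g in 1:4) {
    v <- as.vector(y[n, , g, ])
    expect_lt(abs(mean(v)), 1e-5)
    expect_lt(abs(mean(v^2) - 1), 1e-4)
  }
})

test_that("GN conv is batch-size independent; SiLU fixes zero at zero", {
  set.seed(22)
  w <- gn_conv_params(4, 8, k = 3, gn_groups = 4)
  x1 <- rand_fm(4, 6, 6, seed = 23)
  x2 <- rand_fm(4, 6, 6, seed = 24)
  batch <- array(0, c(2, 4, 6, 6))
  batch[1, , , ] <- x1; batch[2, , , ] <- x2
  yb <- gn_conv_forward(batch, w)
  expect_equal(gn_conv_forward(x1, w), yb[1, , , ], tolerance = 1e-12)
  expect_equal(gn_conv_forward(x2, w), yb[2, , , ], tolerance = 1e-12)
  # zero pre-activation maps to zero output
  w0 <- gn_conv_params(4, 8, gn_groups = 4)
  w0$params$w[] <- 0; w0$params$gamma[] <- 0
  expect_equal(max(abs(gn_conv_forward(x1, w0))), 0)
  expect_error(gn_conv_params(4, 6, gn_groups = 4), "divisible")
})

test_that("shared stacks make the head lighter than three decoupled stacks", {
  cfg <- head_config(c(16, 32, 64), hidden_channels = 16, num_classes = 5,
                     reg_max = 4)
  set.seed(25)
  p <- ssldh_params(cfg)
  total <- count_params(p)
  adapters <- sum(vapply(1:3, function(i)
    count_params(p$children[[paste0("ad_", i)]]), numeric(1)))
  shared <- sum(vapply(c("s1", "f1", "f2", "s2", "reg", "cls"), function(nm)
    count_params(p$children[[nm]]), numeric(1)))
  expect_identical(total, adapters + shared + 3)   # + per-level scales
  # three independent copies of the shared stack would cost 3x `shared`
  expect_lt(total, adapters + 3 * shared)
})

test_that("ssldh_forward checks arity/channels and preserves level dims", {
  cfg <- head_config(c(8, 16, 32), hidden_channels = 16, num_classes = 3,
                     reg_max = 4)
  set.seed(26)
  p <- ssldh_params(cfg)
  p3 <- rand_fm(8, 8, 8); p4 <- rand_fm(16, 4, 4); p5 <- rand_fm(32, 2, 2)
  out <- ssldh_forward(p3, p4, p5, cfg, p)
  expect_identical(dim(out$reg[[1]])[3:4], c(8L, 8L))
  expect_identical(dim(out$reg[[3]])[3:4], c(2L, 2L))
  expect_identical(dim(out$reg[[2]])[2], 16L)      # 4 * reg_max channels
  expect_identical(dim(out$cls[[2]])[2], 3L)
  expect_error(ssldh_forward(p3, p4, NULL, cfg, p), "three pyramid levels")
  expect_error(ssldh_forward(p4, p4, p5, cfg, p), "channels")
})

test_that("a zero level scale silences regression but not classification", {
  cfg <- head_config(c(8, 16, 32), hidden_channels = 16, num_classes = 3,
                     reg_max = 4)
  set.seed(27)
  p <- ssldh_params(cfg)
  p$params$scales[2] <- 0
  out <- ssldh_forward(rand_fm(8, 8, 8), rand_fm(16, 4, 4), rand_fm(32, 2, 2),
                       cfg, p)
  expect_equal(max(abs(out$reg[[2]])), 0)
  expect_gt(max(abs(out$cls[[2]])), 0)
  expect_gt(max(abs(out$reg[[1]])), 0)
})

test_that("decoding one-hot and uniform bin distributions is exact", {
  cfg <- head_config(c(8, 16, 32), num_classes = 2, reg_max = 8,
                     hidden_channels = 16)
  R <- 8
  mk_raw <- function(regfill) {
    reg <- lapply(1:3, function(i) array(regfill, c(1, 4 * R, 1, 1)))
    cls <- lapply(1:3, function(i) array(10, c(1, 2, 1, 1)))  # conf ~ 1
    list(reg = reg, cls = cls)
  }
  # point mass at bin k: logits one-hot scaled large
  k <- 5
  reg <- array(-1e4, c(1, 4 * R, 1, 1))
  for (s in 1:4) reg[1, (s - 1) * R + k + 1, 1, 1] <- 1e4
  raw <- list(reg = lapply(1:3, function(i) reg),
              cls = lapply(1:3, function(i) array(10, c(1, 2, 1, 1))))
  dets <- decode_boxes(raw, cfg, conf_threshold = 0.5, img_size = 10000)
  # the right/bottom distances are k * stride from the cell center at
  # 0.5 * stride (the left/top sides clip at the image edge)
  expect_equal(sort(unique(round(dets$x2, 6))),
               sort((k + 0.5) * cfg$level_strides))
  expect_equal(sort(unique(round(dets$y2, 6))),
               sort((k + 0.5) * cfg$level_strides))
  expect_true(all(dets$x1 == 0))
  # uniform distribution decodes to (R-1)/2 * stride
  rawu <- mk_raw(0)
  detsu <- decode_boxes(rawu, cfg, conf_threshold = 0.5, img_size = 10000)
  expect_equal(sort(unique(round(detsu$x2, 6))),
               sort(((R - 1) / 2 + 0.5) * cfg$level_strides))
})

test_that("vectorized decode equals a cell-by-cell loop oracle", {
  cfg <- head_config(c(8, 16, 32), num_classes = 3, reg_max = 4,
                     hidden_channels = 16)
  R <- 4
  set.seed(28)
  raw <- list(reg = lapply(1:3, function(i) array(rnorm(4 * R * 4), c(1, 4 * R, 2, 2))),
              cls = lapply(1:3, function(i) array(rnorm(12), c(1, 3, 2, 2))))
  dets <- decode_boxes(raw, cfg, conf_threshold = 0, img_size = 64)
  # oracle: explicit loops
  expected <- NULL
  for (i in 1:3) {
    s <- cfg$level_strides[i]
    for (hh in 1:2) for (ww in 1:2) {
      dist <- numeric(4)
      for (sd in 1:4) {
        z <- raw$reg[[i]][1, (sd - 1) * R + 1:R, hh, ww]
        pz <- exp(z - max(z)); pz <- pz / sum(pz)
        dist[sd] <- sum(pz * 0:(R - 1))
      }
      cx <- (ww - 0.5) * s; cy <- (hh - 0.5) * s
      for (cl in 1:3) {
        conf <- 1 / (1 + exp(-raw$cls[[i]][1, cl, hh, ww]))
        expected <- rbind(expected, c(cl - 1, conf,
                                      max(0, min(64, cx - dist[1] * s)),
                                      max(0, min(64, cy - dist[2] * s)),
                                      max(0, min(64, cx + dist[3] * s)),
                                      max(0, min(64, cy + dist[4] * s))))
      }
    }
  }
  key <- function(m) {
    m <- m[order(m[, 2], m[, 3], m[, 4]), , drop = FALSE]
    round(m, 8)
  }
  expect_equal(key(as.matrix(dets)), key(expected), ignore_attr = TRUE)
})

test_that("decoded boxes are ordered and inside the image bounds", {
  cfg <- head_config(c(8, 16, 32), num_classes = 2, reg_max = 16,
                     hidden_channels = 16)
  set.seed(29)
  raw <- list(reg = lapply(1:3, function(i)
                array(rnorm(64 * 16, sd = 3), c(1, 64, 4, 4))),
              cls = lapply(1:3, function(i) array(rnorm(32), c(1, 2, 4, 4))))
  dets <- decode_boxes(raw, cfg, conf_threshold = 0, img_size = 128)
  expect_true(all(dets$x1 <= dets$x2 + 1e-12))
  expect_true(all(dets$y1 <= dets$y2 + 1e-12))
  expect_true(all(dets$x1 >= 0 & dets$x2 <= 128))
  expect_true(all(dets$y1 >= 0 & dets$y2 <= 128))
})
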