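# model assembly: variants, numbering, checkpoints, augmentation, NMS, training

test_that("ablation variants are constructible and strictly ordered in size", {
  set.seed(51)
  models <- lapply(c("baseline", "star", "star-ema", "bcs"),
                   function(v) build_model(variant_config(v)))
  p <- vapply(models, count_params, numeric(1))
  names(p) <- c("baseline", "star", "star-ema", "bcs")
  expect_lt(p["star"], p["baseline"])        # star blocks are lighter
  expect_gt(p["star-ema"], p["star"])        # attention adds a little back
  expect_lt(p["bcs"], p["star-ema"])         # shared head removes the most
  expect_lt(p["bcs"], p["baseline"])         # overall reduction
  expect_error(model_config(input_size = 100), "divisible by 32")
})

test_that("layer numbering is stable and exposes the distillation sites", {
  cfg <- variant_config("bcs", input_size = 64)
  set.seed(52); m1 <- build_model(cfg)
  set.seed(53); m2 <- build_model(cfg)
  ids1 <- vapply(m1$rows, function(r) r$i, integer(1))
  expect_identical(ids1, 0:22)
  expect_identical(m1$rows, m2$rows)
  x <- array(runif(3 * 64 * 64), c(1, 3, 64, 64))
  forward_model(m1, x)
  for (idx in c("12", "15", "18", "21")) {
    fm <- m1$outs[[idx]]
    expect_false(is.null(fm))
    expect_identical(length(dim(fm)), 4L)
  }
  # the four neck fusion outputs carry the expected widths (n-scale)
  expect_identical(dim(m1$outs[["12"]])[2], 128L)
  expect_identical(dim(m1$outs[["15"]])[2], 64L)
  expect_identical(dim(m1$outs[["18"]])[2], 128L)
  expect_identical(dim(m1$outs[["21"]])[2], 256L)
})

test_that("pyramid grids follow the input size; 640 gives 80/40/20", {
  set.seed(54)
  m <- build_model(variant_config("bcs"))
  x <- array(0.5, c(1, 3, 640, 640))
  out <- forward_model(m, x)
  expect_identical(vapply(out$reg, function(a) dim(a)[3], integer(1)),
                   c(80L, 40L, 20L))
  expect_identical(vapply(out$reg, function(a) dim(a)[4], integer(1)),
                   c(80L, 40L, 20L))
  # any other multiple of 32 scales the grids accordingly
  x2 <- array(0.5, c(1, 3, 128, 192))
  out2 <- forward_model(m, x2)
  expect_identical(vapply(out2$cls, function(a) dim(a)[3], integer(1)),
                   c(16L, 8L, 4L))
  expect_identical(vapply(out2$cls, function(a) dim(a)[4], integer(1)),
                   c(24L, 12L, 6L))
})

test_that("checkpoints round-trip bit-exactly and half is close", {
  set.seed(55)
  m <- build_model(variant_config("star", input_size = 64))
  x <- array(runif(3 * 64 * 64), c(1, 3, 64, 64))
  o1 <- forward_model(m, x)
  tmp <- tempfile()
  save_checkpoint(m, tmp, "double")
  m2 <- load_checkpoint(tmp)
  expect_identical(forward_model(m2, x), o1)
  save_checkpoint(m, tmp, "half")
  m3 <- load_checkpoint(tmp)
  expect_lt(max(abs(forward_model(m3, x)$cls[[1]] - o1$cls[[1]])), 0.05)
})

test_that("augmentation: identity config, flip geometry, seeded repeats", {
  set.seed(56)
  img <- rand_fm(3, 24, 32)
  img <- (img - min(img)) / diff(range(img))
  boxes <- cbind(1, 0.4, 0.6, 0.2, 0.3)
  off <- list(hsv_h = 0, hsv_s = 0, hsv_v = 0, translate = 0, scale = 0,
              flipud = 0, fliplr = 0)
  a <- augment_sample(img, boxes, off)
  expect_equal(a$img, img)
  expect_equal(a$boxes, boxes, ignore_attr = TRUE)
  # guaranteed horizontal flip: cx -> 1 - cx, w unchanged
  fl <- off; fl$fliplr <- 1
  b <- augment_sample(img, boxes, fl)
  expect_equal(b$boxes[1, 2], 1 - 0.4, tolerance = 1e-12)
  expect_equal(b$boxes[1, 4], 0.2, tolerance = 1e-12)
  expect_equal(b$img[, , 32:1], img)
  # full pipeline is reproducible under a fixed seed
  aug <- list(hsv_h = 0.015, hsv_s = 0.7, hsv_v = 0.4, translate = 0.1,
              scale = 0.5, flipud = 0.5, fliplr = 0.5)
  r1 <- augment_sample(img, boxes, aug, rng = 99)
  r2 <- augment_sample(img, boxes, aug, rng = 99)
  expect_identical(r1, r2)
})

test_that("greedy NMS equals an exhaustive reference on random boxes", {
  ref_nms <- function(dets, thr) {
    keep <- logical(nrow(dets))
    for (cl in unique(dets$class_id)) {
      idx <- which(dets$class_id == cl)
      idx <- idx[order(-dets$confidence[idx], idx)]
      chosen <- integer()
      for (i in idx) {
        ok <- TRUE
        for (j in chosen) {
          bi <- as.numeric(dets[i, c("x1", "y1", "x2", "y2")])
          bj <- as.numeric(dets[j, c("x1", "y1", "x2", "y2")])
          ix <- max(0, min(bi[3], bj[3]) - max(bi[1], bj[1]))
          iy <- max(0, min(bi[4], bj[4]) - max(bi[2], bj[2]))
          inter <- ix * iy
          un <- (bi[3] - bi[1]) * (bi[4] - bi[2]) +
            (bj[3] - bj[1]) * (bj[4] - bj[2]) - inter
          if (inter / un > thr) { ok <- FALSE; break }
        }
        if (ok) chosen <- c(chosen, i)
      }
      keep[chosen] <- TRUE
    }
    dets[keep, , drop = FALSE]
  }
  # trivial cases
  two <- data.frame(class_id = c(0, 0), confidence = c(0.9, 0.8),
                    x1 = c(10, 10), y1 = c(10, 10), x2 = c(30, 30),
                    y2 = c(30, 30))
  expect_identical(nrow(nms(two, 0.5)), 1L)
  expect_equal(nms(two, 0.5)$confidence, 0.9)
  disjoint <- data.frame(class_id = c(0, 0), confidence = c(0.9, 0.8),
                         x1 = c(0, 50), y1 = c(0, 50), x2 = c(10, 60),
                         y2 = c(10, 60))
  expect_identical(nrow(nms(disjoint, 0.5)), 2L)
  # 20 random boxes vs the reference
  set.seed(57)
  for (rep in 1:5) {
    n <- 20
    x1 <- runif(n, 0, 80); y1 <- runif(n, 0, 80)
    dets <- data.frame(class_id = sample(0:2, n, TRUE),
                       confidence = runif(n),
                       x1 = x1, y1 = y1,
                       x2 = x1 + runif(n, 5, 40), y2 = y1 + runif(n, 5, 40))
    expect_identical(nms(dets, 0.5), ref_nms(dets, 0.5))
    expect_identical(nms(dets, 0.7), ref_nms(dets, 0.7))
  }
})

test_that("training runs with the stated schedule and finite losses", {
  set.seed(58)
  m <- build_model(variant_config("bcs", input_size = 64))
  samples <- lapply(1:6, function(i) {
    img <- array(runif(3 * 64 * 64, 0.2, 0.4), c(3, 64, 64))
    cx <- runif(1, 0.3, 0.7); cy <- runif(1, 0.3, 0.7)
    img[, round(cy * 64) + (-6:6), round(cx * 64) + (-8:8)] <- 0.9
    list(img = img, boxes_norm = cbind(i %% 5, cx, cy, 17 / 64, 13 / 64))
  })
  cfg <- train_config(epochs = 2, batch_size = 3, input_size = 64, seed = 1)
  log <- train_model(m, samples, cfg, augment = FALSE)
  expect_identical(nrow(log), 2L)
  expect_equal(log$lr[1], 0.01)               # initial learning rate
  expect_true(all(is.finite(log$total)))
  expect_true(all(c("box", "cls", "dfl") %in% names(log)))
  expect_error(train_model(m, list(), cfg), "empty dataset")
})
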