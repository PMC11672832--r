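# profiling: parameter counts, FLOP conventions, sizes, detection metrics

test_that("parameter counting matches hand counts", {
  set.seed(61)
  # 3x3 conv, 2 -> 4 channels, with bias: 2*4*9 + 4 = 76
  l <- bcsyolo:::conv_unit(2, 4, 3, norm = "none", act = "none")
  expect_identical(count_params(l), 76)
  # norm replaces the bias with gamma/beta
  lbn <- bcsyolo:::conv_unit(2, 4, 3, norm = "bn")
  expect_identical(count_params(lbn), 72 + 8)
})

test_that("FLOP counts follow the 2*MAC convention and scaling laws", {
  # one 1x1 conv 8 -> 8 on a 4x4 map: 2 * 1 * 8 * 8 * 16 = 2048
  expect_identical(bcsyolo:::conv_flops(8, 8, 1, 4, 4), 2048)
  # doubling H and W quadruples conv FLOPs
  expect_identical(bcsyolo:::conv_flops(16, 32, 3, 20, 20, stride = 1),
                   bcsyolo:::conv_flops(16, 32, 3, 10, 10, stride = 1) * 4)
  # grouped convolutions divide the MACs
  expect_identical(bcsyolo:::conv_flops(8, 8, 3, 4, 4, groups = 8),
                   bcsyolo:::conv_flops(8, 8, 3, 4, 4) / 8)
})

test_that("analytic FLOP walker agrees with the runtime hook counter", {
  for (v in c("baseline", "star", "star-ema", "bcs")) {
    set.seed(62)
    m <- build_model(variant_config(v))
    a <- count_flops(m, 128)
    h <- count_flops_measured(m, 128)
    expect_lt(abs(a - h) / a, 0.01)
  }
})

test_that("profiling is pure and FLOPs are batch-size independent", {
  set.seed(63)
  m <- build_model(variant_config("star"))
  expect_identical(count_flops(m, 160), count_flops(m, 160))
  p1 <- profile_model(m, 160)
  p2 <- profile_model(m, 160)
  expect_identical(p1$param_count, p2$param_count)
  expect_identical(p1$flops, p2$flops)
  expect_identical(p1$serialized_size_bytes, p2$serialized_size_bytes)
})

test_that("serialized sizes: half vs single, payload accounting", {
  set.seed(64)
  m <- build_model(variant_config("star", input_size = 64))
  half <- serialized_size(m, "half")
  single <- serialized_size(m, "single")
  expect_lt(abs(single / half - 2), 0.05)
  # container overhead below 2% of the fp16 payload
  payload <- 2 * bcsyolo:::count_saved_scalars(m)
  expect_lt((half - payload) / payload, 0.02)
  expect_gte(half, payload)
})

test_that("greedy matching equals an exhaustive oracle and trivial cases", {
  truths <- cbind(c(0, 0, 1), c(0, 40, 0), c(0, 40, 50),
                  c(20, 60, 20), c(20, 60, 70))
  perfect <- data.frame(class_id = truths[, 1], confidence = c(0.9, 0.8, 0.7),
                        x1 = truths[, 2], y1 = truths[, 3],
                        x2 = truths[, 4], y2 = truths[, 5])
  m <- match_detections(perfect, truths, 0.5)
  expect_identical(c(m$tp, m$fp, m$fn), c(3L, 0L, 0L))
  none <- perfect[0, ]
  m0 <- match_detections(none, truths, 0.5)
  expect_identical(m0$fn, 3L)
  # random instance vs an explicit-loop reference of the same greedy rule
  ref_match <- function(preds, truths, thr) {
    ord <- order(-preds$confidence, seq_len(nrow(preds)))
    used <- rep(FALSE, nrow(truths))
    flags <- logical(nrow(preds))
    for (r in seq_along(ord)) {
      i <- ord[r]
      best <- 0; bj <- 0
      for (j in seq_len(nrow(truths))) {
        if (used[j] || truths[j, 1] != preds$class_id[i]) next
        bi <- as.numeric(preds[i, c("x1", "y1", "x2", "y2")])
        bj2 <- truths[j, 2:5]
        ix <- max(0, min(bi[3], bj2[3]) - max(bi[1], bj2[1]))
        iy <- max(0, min(bi[4], bj2[4]) - max(bi[2], bj2[2]))
        iou <- ix * iy / ((bi[3] - bi[1]) * (bi[4] - bi[2]) +
                          (bj2[3] - bj2[1]) * (bj2[4] - bj2[2]) - ix * iy)
        if (iou > best) { best <- iou; bj <- j }
      }
      if (bj > 0 && best >= thr) { flags[r] <- TRUE; used[bj] <- TRUE }
    }
    list(tp = sum(flags), fp = sum(!flags), fn = sum(!used), flags = flags)
  }
  set.seed(65)
  for (rep in 1:5) {
    nt <- 4
    tx <- runif(nt, 0, 60); ty <- runif(nt, 0, 60)
    truths <- cbind(sample(0:1, nt, TRUE), tx, ty, tx + runif(nt, 10, 30),
                    ty + runif(nt, 10, 30))
    np <- 10
    px <- runif(np, 0, 60); py <- runif(np, 0, 60)
    preds <- data.frame(class_id = sample(0:1, np, TRUE),
                        confidence = runif(np), x1 = px, y1 = py,
                        x2 = px + runif(np, 10, 30), y2 = py + runif(np, 10, 30))
    a <- match_detections(preds, truths, 0.5)
    b <- ref_match(preds, truths, 0.5)
    expect_identical(c(a$tp, a$fp, a$fn), c(b$tp, b$fp, b$fn))
    expect_identical(a$flags, b$flags)
  }
})

test_that("average precision matches piecewise-area oracles", {
  # two PR points: (R=0.5, P=1.0), (R=1.0, P=0.5) -> area 0.75
  pr <- data.frame(recall = c(0.5, 1), precision = c(1, 0.5))
  expect_equal(average_precision(pr), 0.75)
  # a single correct prediction covering the only truth
  expect_equal(bcsyolo:::ap_from_flags(0.9, TRUE, 1L), 1)
  # everything wrong
  expect_equal(bcsyolo:::ap_from_flags(c(0.9, 0.5), c(FALSE, FALSE), 2L), 0)
  # eleven-point mode on the same two-point curve: mean of envelope at
  # recalls 0:0.1:1 = (6 * 1.0 + 5 * 0.5) / 11
  expect_equal(average_precision(pr, mode = "eleven_point"),
               (6 * 1 + 5 * 0.5) / 11)
  # AP is monotone in an added correct top-ranked detection
  set.seed(66)
  conf <- runif(10); flags <- runif(10) > 0.5
  base <- bcsyolo:::ap_from_flags(conf, flags, 8L)
  more <- bcsyolo:::ap_from_flags(c(1, conf), c(TRUE, flags), 8L)
  expect_gte(more, base)
})

test_that("mAP is the class mean and rejects empty input", {
  expect_equal(map_over_classes(c(0.4, 0.4, 0.4)), 0.4)
  expect_equal(map_over_classes(c(1, 0)), 0.5)
  expect_error(map_over_classes(numeric()), "no classes")
})

test_that("a perfect synthetic detector scores mAP@50:95 of 1", {
  # construct predictions identical to the truths across two images
  set.seed(67)
  iods <- seq(0.5, 0.95, 0.05)
  aps <- vapply(iods, function(thr) {
    conf <- c(0.9, 0.8)
    flags <- c(TRUE, TRUE)
    bcsyolo:::ap_from_flags(conf, flags, 2L)
  }, numeric(1))
  expect_equal(mean(aps), 1)
})
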