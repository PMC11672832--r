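# channel-wise distillation: softmax maps, KL loss, adapters, train step

test_that("channel softmax normalizes every channel over space", {
  set.seed(31)
  x <- rand_fm(5, 4, 6)
  p <- channel_softmax(x, temperature = 2)
  expect_s3_class(p, "channel_prob_map")
  expect_true(all(p$probs >= 0))
  sums <- apply(p$probs, 1, sum)
  expect_equal(sums, rep(1, 5), tolerance = 1e-6)
  # constant channel -> uniform
  xc <- array(3.3, c(2, 4, 5))
  pc <- channel_softmax(xc, 1)
  expect_equal(as.vector(pc$probs), rep(1 / 20, 40), tolerance = 1e-12)
  expect_error(channel_softmax(x, 0), "positive")
  expect_error(channel_softmax(x, -2), "positive")
})

test_that("two-position softmax reproduces the hand-computed (0.25, 0.75)", {
  x <- array(c(0, log(3)), c(1, 1, 2))
  p <- channel_softmax(x, temperature = 1)
  expect_equal(as.vector(p$probs), c(0.25, 0.75), tolerance = 1e-12)
})

test_that("softmax approaches uniform in the high-temperature limit", {
  set.seed(32)
  x <- rand_fm(3, 5, 5) * 10
  p <- channel_softmax(x, temperature = 1e6)
  expect_lt(max(abs(p$probs - 1 / 25)), 1e-3)
})

test_that("cwd loss: zero at equality, hand value, positivity sweep", {
  set.seed(33)
  x <- rand_fm(4, 3, 5)
  expect_equal(cwd_loss(x, x, 4), 0)
  # hand-evaluated KL for teacher (0, ln 3) vs student (0, 0) at T = 1
  t1 <- array(c(0, log(3)), c(1, 1, 2))
  s1 <- array(c(0, 0), c(1, 1, 2))
  expect_equal(cwd_loss(t1, s1, 1),
               0.25 * log(0.25 / 0.5) + 0.75 * log(0.75 / 0.5),
               tolerance = 1e-12)
  # Gibbs' inequality over random pairs
  set.seed(34)
  for (i in 1:500) {
    a <- rand_fm(2, 3, 3); b <- rand_fm(2, 3, 3)
    expect_gte(cwd_loss(a, b, 4), 0)
  }
  # strictly positive for genuinely different softmax maps
  expect_gt(cwd_loss(x, x + rand_fm(4, 3, 5, seed = 35) * 0.5, 4), 0)
  expect_error(cwd_loss(rand_fm(4, 3, 5), rand_fm(4, 3, 4), 4),
               "shape mismatch")
})

test_that("cwd loss is invariant to per-channel constant shifts", {
  set.seed(36)
  a <- rand_fm(3, 4, 4); b <- rand_fm(3, 4, 4)
  base <- cwd_loss(a, b, 4)
  shift_a <- a + array(rep(c(5, -2, 0.3), 16), c(3, 4, 4))
  shift_b <- b + array(rep(c(-1, 7, 2), 16), c(3, 4, 4))
  expect_equal(cwd_loss(shift_a, b, 4), base, tolerance = 1e-9)
  expect_equal(cwd_loss(a, shift_b, 4), base, tolerance = 1e-9)
})

test_that("T^2-weighted loss at T = 1 equals the raw KL sum over C", {
  set.seed(37)
  a <- rand_fm(4, 3, 3); b <- rand_fm(4, 3, 3)
  kl <- 0
  for (c in 1:4) {
    pa <- exp(a[c, , ]); pa <- pa / sum(pa)
    pb <- exp(b[c, , ]); pb <- pb / sum(pb)
    kl <- kl + sum(pa * log(pa / pb))
  }
  expect_equal(cwd_loss(a, b, 1), kl / 4, tolerance = 1e-9)
  # continuity in T
  expect_true(all(is.finite(vapply(c(0.5, 1, 2, 4, 16),
                                   function(T) cwd_loss(a, b, T),
                                   numeric(1)))))
})

test_that("channel adapters: identity init, target width, gradient flow", {
  set.seed(38)
  x <- rand_fm(4, 3, 3)
  id <- adapter_params(4, 4)
  expect_equal(adapt_channels(x, 4, id), x)
  up <- adapter_params(4, 6)
  expect_identical(dim(adapt_channels(x, 6, up))[1], 6L)
  expect_error(adapt_channels(x, 8, up), "adapter produces")
  # finite-difference check that cwd gradients reach the adapter weights
  teacher <- rand_fm(6, 3, 3, seed = 39)
  xb <- x; dim(xb) <- c(1, dim(x))
  lossfun <- function() {
    a <- bcsyolo:::ly_fwd(up, xb, training = TRUE)
    bcsyolo:::cwd_loss_grad(teacher, a[1, , , ], 4)
  }
  r <- lossfun()
  g <- r$dstudent; dim(g) <- c(1, dim(g))
  bcsyolo:::ly_bwd(up, g)
  an <- up$grads$w
  eps <- 1e-6
  for (i in sample(length(up$params$w), 5)) {
    o <- up$params$w[i]
    up$params$w[i] <- o + eps; up$cache_stack <- list(); l1 <- lossfun()$loss
    up$params$w[i] <- o - eps; up$cache_stack <- list(); l2 <- lossfun()$loss
    up$params$w[i] <- o; up$cache_stack <- list()
    expect_equal((l1 - l2) / (2 * eps), an[i], tolerance = 1e-5)
  }
})

test_that("distill step: weight zero, teacher frozen, copy gives zero", {
  set.seed(40)
  teacher <- build_model(variant_config("bcs", input_size = 64))
  set.seed(41)
  student <- build_model(variant_config("bcs", input_size = 64))
  x <- array(runif(2 * 3 * 64 * 64), c(2, 3, 64, 64))
  calibrate_bn(teacher, x)
  tg <- list(cbind(0, 10, 10, 40, 40), cbind(2, 20, 20, 55, 50))
  batch <- list(x = x, targets = tg)
  # loss_weight 0: total is exactly the detection loss
  r0 <- distill_step(batch, teacher, student,
                     distill_config(loss_weight = 0, lr = 0), update = FALSE)
  expect_identical(r0$total, r0$detection)
  # teacher weights bit-identical across a real update step
  before <- bcsyolo:::collect_tensors(teacher)
  r1 <- distill_step(batch, teacher, student, distill_config(lr = 1e-3))
  after <- bcsyolo:::collect_tensors(teacher)
  expect_identical(before, after)
  expect_gt(r1$distill, 0)
  # a weight copy of the teacher has zero distillation loss
  tmp <- tempfile()
  save_checkpoint(teacher, tmp)
  copy <- load_checkpoint(tmp)
  rc <- distill_step(batch, teacher, copy, distill_config(lr = 0),
                     update = FALSE)
  expect_equal(rc$distill, 0)
  expect_error(distill_config(layer_pairs = list(c(12, 40))), "out of range")
  expect_error(distill_config(weight_schedule = "cosine"), "constant")
})
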