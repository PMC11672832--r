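# shared test helpers: small random feature maps, an independent "by hand"
# conv unit evaluation (plain R loops, no shared code with the engine), and
# a cached tiny synthetic dataset.

rand_fm <- function(C, H, W, N = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(N)) array(stats::rnorm(C * H * W), c(C, H, W))
  else array(stats::rnorm(N * C * H * W), c(N, C, H, W))
}

# reference 1x1 convolution as explicit matrix algebra on a (C,H,W) map
ref_conv1x1 <- function(x, w, b = NULL) {
  d <- dim(x)
  m <- matrix(x, d[1L], d[2L] * d[3L])
  wm <- matrix(w, dim(w)[1L], dim(w)[2L])
  y <- wm %*% m
  if (!is.null(b)) y <- y + b
  array(y, c(dim(w)[1L], d[2L], d[3L]))
}

ref_sigmoid <- function(x) 1 / (1 + exp(-x))
ref_silu <- function(x) x * ref_sigmoid(x)

# eval-mode BatchNorm with freshly initialized buffers (rm = 0, rv = 1)
ref_bn_init <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  sweep(sweep(x, 1L, gamma / sqrt(1 + eps), "*"), 1L, beta, "+")
}

# one shared tiny dataset on disk per test session
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "bcsy_test_ds")
      cfg <- synth_config(n_per_class = rep(3L, 5L),
                          image_size = c(260L, 144L), seed = 7L)
      cache <<- list(man = generate_dataset(cfg, dir), cfg = cfg, dir = dir)
    }
    cache
  }
})
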