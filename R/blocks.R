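# Star / EMA block surface ------------------------------------------------

#' Star operation: element-wise product of two features
#'
#' The star operation fuses two linearly transformed copies of a feature by
#' element-wise multiplication. For linear maps `w1`, `w2` applied to a
#' bias-augmented input `x` of length `d + 1`, `(w1' x) * (w2' x)` expands to
#' the sum over all pairwise monomials `x_i x_j`, so a single multiplication
#' implicitly spans a feature space of dimension `(d+1)(d+2)/2`.
#'
#' @param a,b numeric vectors or arrays of identical shape.
#' @return element-wise product, same shape.
#' @export
star_product <- function(a, b) {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (!identical(da, db))
    stop("star_product: shape mismatch (", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"), ")")
  a * b
}

#' Implicit monomial count of the star operation
#'
#' Number of distinct monomials `x_i x_j` (i <= j) over a bias-augmented
#' input of length `d + 1`: `(d+1)(d+2)/2`. This is the combinatorial count
#' of the implicit feature space the star operation spans.
#'
#' @param d non-negative integer input dimension (before bias augmentation).
#' @return integer monomial count.
#' @export
implicit_monomial_count <- function(d) {
  if (length(d) != 1L || is.na(d) || d < 0 || d != floor(d))
    stop("d must be a single non-negative integer")
  as.integer((d + 1) * (d + 2) / 2)
}

#' Star block parameters
#'
#' Constructs the learnable state of one star block: depthwise conv,
#' two parallel pointwise expansion maps fused by an element-wise product
#' (activation on branch 1 only), pointwise projection, second depthwise
#' conv, and an optional residual connection. Weights are drawn from the
#' current RNG state.
#'
#' @param in_channels input/output channel count.
#' @param expand_ratio hidden width multiplier between the two pointwise
#'   maps (default 3).
#' @param dw_kernel odd depthwise kernel size (default 5).
#' @param act activation on branch 1: `"silu"` (default) or `"relu6"`.
#' @param residual enable the residual connection.
#' @return a star block layer object (also a valid parameter container).
#' @export
star_block_params <- function(in_channels, expand_ratio = 3, dw_kernel = 5L,
                              act = c("silu", "relu6"), residual = TRUE) {
  act <- match.arg(act)
  star_block_layer(as.integer(in_channels), expand_ratio, dw_kernel, act,
                   residual)
}

#' Forward pass of a star block
#'
#' @param x feature map, `c(C, H, W)` or `c(N, C, H, W)`.
#' @param p parameters from [star_block_params()].
#' @return feature map of the same shape as `x`.
#' @export
star_block_forward <- function(x, p) {
  if (!inherits(p, "bcsy_star_block")) stop("p must come from star_block_params()")
  nm <- as_nchw(x)
  if (nchan(nm$x) != p$c)
    stop("channel mismatch: input has ", nchan(nm$x), ", block expects ", p$c)
  un_nchw(ly_fwd(p, nm$x, training = FALSE), nm$batched)
}

#' EMA attention parameters
#'
#' @param channels input channel count.
#' @param groups number of channel sub-feature groups `G`; must divide
#'   `channels`. Default: the largest divisor of `channels` that is <= 4
#'   (the grouping used by the assembled models).
#' @param variant `"paper_eqs"` for the directional-pooling gate alone
#'   (the normative description), `"full_cited"` for the complete cited
#'   module with 3x3 branch and cross-spatial interaction.
#' @return an EMA layer object.
#' @export
ema_params <- function(channels, groups = NULL,
                       variant = c("paper_eqs", "full_cited")) {
  variant <- match.arg(variant)
  channels <- as.integer(channels)
  if (is.null(groups)) groups <- largest_divisor_leq(channels, 4L)
  ema_layer(channels, groups, variant)
}

#' Forward pass of the EMA attention module
#'
#' Splits channels into `G` groups; per group pools globally along the width
#' (giving the height descriptor `z^H`) and along the height (`z^W`),
#' concatenates the two descriptors along the spatial axis (H first, then
#' W), applies a shared 1x1 convolution and sigmoid, splits back into
#' per-direction gates, and modulates the input multiplicatively. The
#' `full_cited` variant adds a per-group 3x3 branch and cross-spatial
#' attention weights.
#'
#' @param x feature map, `c(C, H, W)` or `c(N, C, H, W)`.
#' @param p parameters from [ema_params()].
#' @return feature map of the same shape as `x`.
#' @export
ema_forward <- function(x, p) {
  if (!inherits(p, "bcsy_ema")) stop("p must come from ema_params()")
  nm <- as_nchw(x)
  if (nchan(nm$x) %% p$G != 0L)
    stop("channels (", nchan(nm$x), ") not divisible by groups (", p$G, ")")
  if (nchan(nm$x) != p$c)
    stop("channel mismatch: input has ", nchan(nm$x), ", module expects ", p$c)
  un_nchw(ly_fwd(p, nm$x, training = FALSE), nm$batched)
}

#' Directional pooled descriptors of a feature map
#'
#' The two 1D global-average-pool descriptors the EMA gate is built from:
#' `zH(c, i) = mean_j x(c, i, j)` and `zW(c, j) = mean_i x(c, i, j)`.
#'
#' @param x feature map, `c(C, H, W)` or `c(N, C, H, W)`.
#' @return list with `zH` (mean over width) and `zW` (mean over height),
#'   spatial singleton axes dropped.
#' @export
directional_pool <- function(x) {
  nm <- as_nchw(x)
  zh <- pool_w_fw(nm$x)$y
  zw <- pool_h_fw(nm$x)$y
  d <- dim(nm$x)
  dim(zh) <- c(d[1L], d[2L], d[3L])
  dim(zw) <- c(d[1L], d[2L], d[4L])
  if (!nm$batched) {
    dim(zh) <- dim(zh)[-1L]
    dim(zw) <- dim(zw)[-1L]
  }
  list(zH = zh, zW = zw)
}

#' C2f-Star-EMA composite parameters
#'
#' The C2f skeleton (split, n stacked inner blocks with partial
#' concatenation, fuse conv) with star blocks as the inner bottlenecks and
#' the EMA module applied once after the fuse convolution.
#'
#' @param in_channels,out_channels block input/output widths.
#' @param n_blocks number of stacked inner star blocks (>= 1).
#' @param opts options list as in [model_config()].
#' @return a C2f layer object.
#' @export
c2f_star_ema_params <- function(in_channels, out_channels, n_blocks = 1L,
                                opts = list()) {
  if (n_blocks < 1L) stop("n_blocks must be >= 1")
  c2f_layer(as.integer(in_channels), as.integer(out_channels),
            as.integer(n_blocks), shortcut = FALSE, block = "c2f_star_ema",
            opts = opts)
}

#' Forward pass of the C2f-Star-EMA composite
#'
#' @param x feature map with `in_channels` channels.
#' @param n_blocks number of inner blocks; must match the parameter object.
#' @param params parameters from [c2f_star_ema_params()].
#' @return feature map with `out_channels` channels, same spatial dims.
#' @export
c2f_star_ema_forward <- function(x, n_blocks, params) {
  if (!inherits(params, "bcsy_c2f")) stop("params must come from c2f_star_ema_params()")
  if (n_blocks != params$n)
    stop("n_blocks (", n_blocks, ") does not match parameters (", params$n, ")")
  nm <- as_nchw(x)
  if (nchan(nm$x) != params$cin)
    stop("channel mismatch: input has ", nchan(nm$x), ", block expects ",
         params$cin)
  un_nchw(ly_fwd(params, nm$x, training = FALSE), nm$batched)
}
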