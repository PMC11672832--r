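# Shared GroupNorm lightweight detection head (SSLDH) ---------------------

#' Detection head configuration
#'
#' @param level_channels channels of the three pyramid inputs (P3, P4, P5).
#' @param level_strides strides of the three levels; strictly increasing.
#' @param hidden_channels shared head width (default 56).
#' @param gn_groups GroupNorm groups; default: largest divisor of
#'   `hidden_channels` that is <= 16.
#' @param num_classes number of classes (5 for BCS).
#' @param reg_max regression distribution bins (default 16).
#' @param fc_expand expansion factor of the multiplicative FC interaction.
#' @return a `bcsy_head_config`.
#' @export
head_config <- function(level_channels, level_strides = c(8L, 16L, 32L),
                        hidden_channels = 56L, gn_groups = NULL,
                        num_classes = 5L, reg_max = 16L, fc_expand = 1.5) {
  if (length(level_channels) != 3L || length(level_strides) != 3L)
    stop("exactly 3 pyramid levels are required")
  if (any(diff(level_strides) <= 0)) stop("level_strides must be strictly increasing")
  if (num_classes < 1L) stop("num_classes must be >= 1")
  if (reg_max < 2L) stop("reg_max must be >= 2")
  if (is.null(gn_groups)) gn_groups <- largest_divisor_leq(as.integer(hidden_channels), 16L)
  if (hidden_channels %% gn_groups != 0L)
    stop("hidden_channels must be divisible by gn_groups")
  structure(list(level_channels = as.integer(level_channels),
                 level_strides = as.integer(level_strides),
                 hidden_channels = as.integer(hidden_channels),
                 gn_groups = as.integer(gn_groups),
                 num_classes = as.integer(num_classes),
                 reg_max = as.integer(reg_max), fc_expand = fc_expand),
            class = "bcsy_head_config")
}

#' GroupNorm convolution unit parameters
#'
#' Convolution (no bias) followed by GroupNorm and SiLU. GroupNorm divides
#' the channels into groups normalized independently per sample, which
#' removes the batch-size sensitivity of batch statistics.
#'
#' @param in_channels,out_channels conv widths.
#' @param k kernel size.
#' @param gn_groups group count; must divide `out_channels`.
#' @return a conv unit layer.
#' @export
gn_conv_params <- function(in_channels, out_channels, k = 1L, gn_groups = 16L) {
  if (out_channels %% gn_groups != 0L)
    stop("out_channels (", out_channels, ") not divisible by gn_groups (",
         gn_groups, ")")
  conv_unit(as.integer(in_channels), as.integer(out_channels), as.integer(k),
            norm = "gn", act = "silu", gn_groups = as.integer(gn_groups))
}

#' Forward pass of a GroupNorm convolution
#'
#' @param x feature map, `c(C, H, W)` or `c(N, C, H, W)`.
#' @param weights parameters from [gn_conv_params()].
#' @param gn_groups optional override of the group count.
#' @return feature map.
#' @export
gn_conv_forward <- function(x, weights, gn_groups = NULL) {
  if (!is.null(gn_groups)) {
    if (weights$cout %% gn_groups != 0L)
      stop("channels not divisible by gn_groups")
    weights$gn_groups <- as.integer(gn_groups)
  }
  nm <- as_nchw(x)
  un_nchw(ly_fwd(weights, nm$x, training = FALSE), nm$batched)
}

#' SSLDH parameters
#'
#' @param cfg a [head_config()].
#' @return an SSLDH layer object.
#' @export
ssldh_params <- function(cfg) {
  if (!inherits(cfg, "bcsy_head_config")) stop("cfg must be a head_config")
  ssldh_layer(cfg$level_channels, cfg$num_classes, cfg$reg_max,
              hidden = cfg$hidden_channels, gn_groups = cfg$gn_groups,
              fc_expand = cfg$fc_expand)
}

#' Forward pass of the SSLDH head
#'
#' Per level: a level-specific GroupNorm 1x1 adapter to the shared width,
#' a shared GroupNorm 3x3 conv, the star interaction (two parallel 1x1
#' linear maps fused by element-wise multiplication, activation on branch
#' one), a second shared GroupNorm 3x3 conv, and the shared regression /
#' classification output convolutions; a per-level learnable scale is
#' applied to the regression branch.
#'
#' @param p3,p4,p5 pyramid feature maps (stride 8/16/32).
#' @param cfg a [head_config()].
#' @param params parameters from [ssldh_params()].
#' @return raw head output: `list(reg = list(3), cls = list(3))` with
#'   `4*reg_max` and `num_classes` channels respectively.
#' @export
ssldh_forward <- function(p3, p4, p5, cfg, params) {
  if (missing(p5) || is.null(p5) || missing(p4) || is.null(p4))
    stop("three pyramid levels are required")
  xs0 <- list(p3, p4, p5)
  nms <- lapply(xs0, as_nchw)
  for (i in 1:3)
    if (nchan(nms[[i]]$x) != cfg$level_channels[i])
      stop("level ", i, " has ", nchan(nms[[i]]$x), " channels, expected ",
           cfg$level_channels[i])
  out <- ly_fwd(params, lapply(nms, `[[`, "x"), training = FALSE)
  structure(out, class = "bcsy_raw_head")
}

# stable softmax over the first dim of an (R x L) matrix
softmax_cols <- function(m) {
  mx <- apply(m, 2L, max)
  e <- exp(sweep(m, 2L, mx))
  sweep(e, 2L, colSums(e), "/")
}

#' Decode raw head output into detections
#'
#' Each cell's regression logits form 4 discrete distributions over
#' `reg_max` bins; the expected bin index (softmax-weighted) gives the
#' distance from the cell-center anchor to each box side in stride units.
#' Classification logits pass through a sigmoid; (cell, class) pairs below
#' `conf_threshold` are dropped. Boxes are returned in pixel xyxy
#' coordinates, clipped to the image bounds.
#'
#' @param raw head output (`list(reg =, cls =)`, batch size 1).
#' @param cfg a [head_config()] (strides, bins, classes).
#' @param conf_threshold confidence threshold in `[0, 1]`.
#' @param img_size image size in pixels, `c(width, height)` or a scalar;
#'   default inferred from the level grids.
#' @return data.frame with columns `class_id` (0-based), `confidence`,
#'   `x1`, `y1`, `x2`, `y2`; possibly zero rows.
#' @export
decode_boxes <- function(raw, cfg, conf_threshold = 0.25, img_size = NULL) {
  R <- cfg$reg_max; nc <- cfg$num_classes
  dets <- vector("list", 3L)
  for (i in 1:3) {
    reg <- raw$reg[[i]]; cls <- raw$cls[[i]]
    dreg <- dim(reg)
    if (length(dreg) == 4L) {
      if (dreg[1L] != 1L) stop("decode_boxes expects batch size 1")
      dim(reg) <- dreg[-1L]; dim(cls) <- dim(cls)[-1L]
    }
    if (dim(reg)[1L] != 4L * R) stop("regression map has wrong channel count")
    if (dim(cls)[1L] != nc) stop("classification map has wrong channel count")
    H <- dim(reg)[2L]; W <- dim(reg)[3L]
    stride <- cfg$level_strides[i]
    if (is.null(img_size)) img_size <- c(W * stride, H * stride)
    if (length(img_size) == 1L) img_size <- c(img_size, img_size)
    L <- H * W
    dist <- matrix(0, 4L, L)
    for (s in 1:4) {
      m <- matrix(reg[(s - 1L) * R + seq_len(R), , ], R, L)
      dist[s, ] <- colSums(softmax_cols(m) * (0:(R - 1L)))
    }
    hh <- ((seq_len(L) - 1L) %% H) + 1L
    ww <- ((seq_len(L) - 1L) %/% H) + 1L
    cx <- (ww - 0.5) * stride
    cy <- (hh - 0.5) * stride
    x1 <- cx - dist[1L, ] * stride; y1 <- cy - dist[2L, ] * stride
    x2 <- cx + dist[3L, ] * stride; y2 <- cy + dist[4L, ] * stride
    conf <- 1 / (1 + exp(-matrix(cls, nc, L)))
    hit <- which(conf >= conf_threshold, arr.ind = TRUE)
    if (nrow(hit) == 0L) { dets[[i]] <- NULL; next }
    cell <- hit[, 2L]
    dets[[i]] <- data.frame(
      class_id = hit[, 1L] - 1L,
      confidence = conf[hit],
      x1 = pmin(pmax(x1[cell], 0), img_size[1L]),
      y1 = pmin(pmax(y1[cell], 0), img_size[2L]),
      x2 = pmin(pmax(x2[cell], 0), img_size[1L]),
      y2 = pmin(pmax(y2[cell], 0), img_size[2L]))
  }
  out <- do.call(rbind, dets)
  if (is.null(out))
    out <- data.frame(class_id = integer(), confidence = numeric(),
                      x1 = numeric(), y1 = numeric(), x2 = numeric(),
                      y2 = numeric())
  out
}
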