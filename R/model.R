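# Model assembly ----------------------------------------------------------
#
# The detector graph follows the YOLOv8 lineage: stem + four C2f backbone
# stages + SPPF, a PAN neck with four C2f fusion blocks, and a three-level
# detection head. Top-level modules carry a stable sequential numbering
# (0..22); the four neck fusion outputs sit at indices 12, 15, 18 and 21,
# which is where distillation hooks attach.

#' Model configuration
#'
#' Describes one architecture variant. `block_variant` selects the inner
#' feature block everywhere a C2f sits (backbone and neck); `head_variant`
#' selects between the baseline decoupled head and the shared GroupNorm
#' lightweight detection head (SSLDH).
#'
#' @param scale model scale, `"n"` (width 0.25) or `"s"` (width 0.5).
#' @param num_classes number of object classes (5 for the BCS task).
#' @param block_variant one of `"c2f_baseline"`, `"c2f_star"`,
#'   `"c2f_star_ema"`.
#' @param head_variant one of `"baseline_decoupled"`, `"ssldh"`.
#' @param input_size network input resolution; must be divisible by 32.
#' @param opts list of block/head options: `star_expand` (pointwise expansion
#'   of the star block, default 3), `dw_kernel` (depthwise kernel, default 5),
#'   `branch_act` (activation on the multiplicative branch, `"silu"` or
#'   `"relu6"`), `ema_groups` (channel groups of the attention module,
#'   default 4), `ema_variant` (`"full_cited"` or `"paper_eqs"`),
#'   `head_hidden` (SSLDH shared width, default 56), `head_fc_expand`
#'   (expansion of the head's multiplicative FC interaction, default 1.5),
#'   `head_shared_outputs` (share the output convolutions across levels,
#'   default TRUE), `reg_max` (regression distribution bins, default 16).
#' @return an object of class `bcsy_config`.
#' @export
model_config <- function(scale = c("n", "s"), num_classes = 5L,
                         block_variant = c("c2f_baseline", "c2f_star",
                                           "c2f_star_ema"),
                         head_variant = c("baseline_decoupled", "ssldh"),
                         input_size = 640L, opts = list()) {
  scale <- match.arg(scale)
  block_variant <- match.arg(block_variant)
  head_variant <- match.arg(head_variant)
  if (input_size %% 32L != 0L) stop("input_size must be divisible by 32")
  if (num_classes < 1L) stop("num_classes must be >= 1")
  defaults <- list(star_expand = 3, dw_kernel = 5L, branch_act = "silu",
                   ema_groups = 4L, ema_variant = "full_cited",
                   head_hidden = 56L, head_fc_expand = 1.5, reg_max = 16L)
  for (nm in names(opts)) defaults[[nm]] <- opts[[nm]]
  structure(list(scale = scale, num_classes = as.integer(num_classes),
                 block_variant = block_variant, head_variant = head_variant,
                 input_size = as.integer(input_size), opts = defaults),
            class = "bcsy_config")
}

#' Named ablation variants
#'
#' Shorthand for the four architecture rows of the ablation: `"baseline"`
#' (plain C2f + decoupled head), `"star"` (C2f-Star), `"star-ema"`
#' (C2f-Star-EMA), `"bcs"` (C2f-Star-EMA + SSLDH), and `"teacher"` (the
#' s-scale baseline used as the distillation teacher).
#'
#' @param name variant name.
#' @param num_classes,input_size,opts passed to [model_config()].
#' @export
variant_config <- function(name = c("baseline", "star", "star-ema", "bcs",
                                    "teacher"),
                           num_classes = 5L, input_size = 640L, opts = list()) {
  name <- match.arg(name)
  switch(name,
    baseline = model_config("n", num_classes, "c2f_baseline",
                            "baseline_decoupled", input_size, opts),
    star = model_config("n", num_classes, "c2f_star", "baseline_decoupled",
                        input_size, opts),
    `star-ema` = model_config("n", num_classes, "c2f_star_ema",
                              "baseline_decoupled", input_size, opts),
    bcs = model_config("n", num_classes, "c2f_star_ema", "ssldh", input_size,
                       opts),
    teacher = model_config("s", num_classes, "c2f_baseline",
                           "baseline_decoupled", input_size, opts))
}

scaled_widths <- function(scale) {
  wm <- if (scale == "n") 0.25 else 0.5
  as.integer(round(c(64, 128, 256, 512, 1024) * wm))
}
scaled_depth <- function(n) max(1L, as.integer(round(n * 0.33)))

# Declarative graph rows: idx, from (-1 = previous), type, args.
graph_spec <- function(cfg) {
  w <- scaled_widths(cfg$scale)
  c1 <- w[1]; c2 <- w[2]; c3 <- w[3]; c4 <- w[4]; c5 <- w[5]
  d1 <- scaled_depth(3L); d2 <- scaled_depth(6L)
  bv <- cfg$block_variant
  row <- function(i, from, type, ...) list(i = i, from = from, type = type,
                                           args = list(...))
  list(
    row(0L, -1L, "conv", cin = 3L, cout = c1, k = 3L, stride = 2L),
    row(1L, -1L, "conv", cin = c1, cout = c2, k = 3L, stride = 2L),
    row(2L, -1L, "c2f", cin = c2, cout = c2, n = d1, shortcut = TRUE, block = bv),
    row(3L, -1L, "conv", cin = c2, cout = c3, k = 3L, stride = 2L),
    row(4L, -1L, "c2f", cin = c3, cout = c3, n = d2, shortcut = TRUE, block = bv),
    row(5L, -1L, "conv", cin = c3, cout = c4, k = 3L, stride = 2L),
    row(6L, -1L, "c2f", cin = c4, cout = c4, n = d2, shortcut = TRUE, block = bv),
    row(7L, -1L, "conv", cin = c4, cout = c5, k = 3L, stride = 2L),
    row(8L, -1L, "c2f", cin = c5, cout = c5, n = d1, shortcut = TRUE, block = bv),
    row(9L, -1L, "sppf", cin = c5, cout = c5),
    row(10L, -1L, "upsample"),
    row(11L, c(10L, 6L), "concat"),
    row(12L, -1L, "c2f", cin = c5 + c4, cout = c4, n = d1, shortcut = FALSE, block = bv),
    row(13L, -1L, "upsample"),
    row(14L, c(13L, 4L), "concat"),
    row(15L, -1L, "c2f", cin = c4 + c3, cout = c3, n = d1, shortcut = FALSE, block = bv),
    row(16L, -1L, "conv", cin = c3, cout = c3, k = 3L, stride = 2L),
    row(17L, c(16L, 12L), "concat"),
    row(18L, -1L, "c2f", cin = c3 + c4, cout = c4, n = d1, shortcut = FALSE, block = bv),
    row(19L, -1L, "conv", cin = c4, cout = c4, k = 3L, stride = 2L),
    row(20L, c(19L, 9L), "concat"),
    row(21L, -1L, "c2f", cin = c4 + c5, cout = c5, n = d1, shortcut = FALSE, block = bv),
    row(22L, c(15L, 18L, 21L), "head", chs = c(c3, c4, c5))
  )
}

#' Build a detector model from a configuration
#'
#' Weights are initialized from the current RNG state; call `set.seed()`
#' first for reproducible initialization. The returned model is an
#' environment holding the layer graph; after a forward pass,
#' `model$outs[["12"]]` etc. expose the hookable feature maps at the
#' canonical indices.
#'
#' @param cfg a [model_config()] object.
#' @return an object of class `bcsy_model`.
#' @export
build_model <- function(cfg) {
  if (!inherits(cfg, "bcsy_config")) stop("cfg must be a bcsy_config")
  rows <- graph_spec(cfg)
  layers <- vector("list", length(rows))
  for (k in seq_along(rows)) {
    r <- rows[[k]]
    a <- r$args
    layers[[k]] <- switch(r$type,
      conv = conv_unit(a$cin, a$cout, a$k, a$stride),
      c2f = c2f_layer(a$cin, a$cout, a$n, a$shortcut, a$block, cfg$opts),
      sppf = sppf_layer(a$cin, a$cout),
      upsample = upsample_layer(),
      concat = new_layer("concat"),
      head = if (cfg$head_variant == "ssldh")
        ssldh_layer(a$chs, cfg$num_classes, cfg$opts$reg_max,
                    hidden = cfg$opts$head_hidden,
                    fc_expand = cfg$opts$head_fc_expand,
                    shared_outputs = cfg$opts$head_shared_outputs %||% TRUE)
      else detect_base_layer(a$chs, cfg$num_classes, cfg$opts$reg_max))
  }
  m <- new.env(parent = emptyenv())
  m$cfg <- cfg
  m$rows <- rows
  m$layers <- layers
  m$strides <- c(8L, 16L, 32L)
  m$outs <- list()
  class(m) <- "bcsy_model"
  m
}

#' Run the detector forward
#'
#' @param model a `bcsy_model`.
#' @param x input image batch, array `c(N, 3, H, W)` or `c(3, H, W)`, values
#'   in `[0, 1]`; H and W must be divisible by 32.
#' @param training logical; training mode enables batch statistics and
#'   gradient caches.
#' @return the raw head output: `list(reg = , cls = )`, three pyramid levels
#'   each. Per-layer outputs are left in `model$outs` keyed by layer index.
#' @export
forward_model <- function(model, x, training = FALSE) {
  nm <- as_nchw(x)
  x <- nm$x
  d <- dim(x)
  if (d[2L] != 3L) stop("expected 3 input channels, got ", d[2L])
  if (d[3L] %% 32L != 0L || d[4L] %% 32L != 0L)
    stop("input spatial dims must be divisible by 32")
  outs <- vector("list", length(model$rows))
  concat_cs <- vector("list", length(model$rows))
  prev <- x
  for (k in seq_along(model$rows)) {
    r <- model$rows[[k]]
    inp <- if (identical(r$from, -1L)) prev
           else lapply(r$from, function(j) outs[[j + 1L]])
    y <- switch(r$type,
      concat = {
        cc <- concat_ch(inp)
        concat_cs[[k]] <- cc$cs
        cc$y
      },
      head = ly_fwd(model$layers[[k]], inp, training),
      ly_fwd(model$layers[[k]], inp, training))
    outs[[k]] <- y
    prev <- y
  }
  model$outs <- stats::setNames(outs, vapply(model$rows, function(r)
    as.character(r$i), character(1L)))
  model$concat_cs <- concat_cs
  model$head_out <- outs[[length(outs)]]
  model$head_out
}

# Reverse pass over the graph. `dhead` matches the head output structure;
# `extra_grads` is a named list (layer index as character) of gradients
# arriving at intermediate outputs, e.g. from distillation losses.
backward_model <- function(model, dhead, extra_grads = list()) {
  n <- length(model$rows)
  douts <- vector("list", n)
  for (nm in names(extra_grads)) {
    k <- as.integer(nm) + 1L
    douts[[k]] <- if (is.null(douts[[k]])) extra_grads[[nm]]
                  else douts[[k]] + extra_grads[[nm]]
  }
  douts[[n]] <- dhead
  for (k in n:1L) {
    dy <- douts[[k]]
    if (is.null(dy)) next
    r <- model$rows[[k]]
    if (r$type == "head") {
      dxs <- ly_bwd(model$layers[[k]], dy)
      for (j in seq_along(r$from)) {
        kk <- r$from[j] + 1L
        douts[[kk]] <- if (is.null(douts[[kk]])) dxs[[j]]
                       else douts[[kk]] + dxs[[j]]
      }
    } else if (r$type == "concat") {
      dxs <- split_ch(dy, model$concat_cs[[k]])
      for (j in seq_along(r$from)) {
        kk <- r$from[j] + 1L
        douts[[kk]] <- if (is.null(douts[[kk]])) dxs[[j]]
                       else douts[[kk]] + dxs[[j]]
      }
    } else {
      dx <- ly_bwd(model$layers[[k]], dy)
      if (k > 1L) {
        kk <- if (identical(r$from, -1L)) k - 1L else r$from + 1L
        douts[[kk]] <- if (is.null(douts[[kk]])) dx else douts[[kk]] + dx
      }
    }
    douts[[k]] <- NULL
  }
  invisible(NULL)
}

#' Calibrate BatchNorm running statistics on a batch
#'
#' Overwrites every BatchNorm layer's running mean/variance with the
#' statistics of one forward pass on `x`. Used before distillation (and
#' before eval of an untrained model) so that inference-mode normalization
#' is well-scaled.
#'
#' @param model a `bcsy_model`, updated in place.
#' @param x image batch `c(N, 3, H, W)`.
#' @export
calibrate_bn <- function(model, x) {
  .engine$bn_calibrate <- TRUE
  on.exit({ .engine$bn_calibrate <- FALSE; clear_caches(model) })
  forward_model(model, x, training = TRUE)
  invisible(model)
}

zero_grads <- function(model) {
  for (l in model$layers) walk_layers(l, function(x, p) x$grads <- list())
  invisible(NULL)
}

clear_caches <- function(model) {
  for (l in model$layers) walk_layers(l, function(x, p) x$cache_stack <- list())
  invisible(NULL)
}

# SGD with classical momentum; weight decay on convolution kernels only;
# gradients clipped to a global norm of `clip_norm` before the update.
sgd_step <- function(model, lr, momentum = 0.937, weight_decay = 0,
                     clip_norm = 10) {
  gsq <- 0
  for (l in model$layers) walk_layers(l, function(e, p) {
    for (nm in names(e$grads)) gsq <<- gsq + sum(e$grads[[nm]]^2)
  })
  scale <- if (clip_norm > 0 && sqrt(gsq) > clip_norm) clip_norm / sqrt(gsq)
           else 1
  step_layer <- function(l, path) {
    if (is.null(l$opt)) l$opt <- list()
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      if (is.null(g)) next
      g <- g * scale
      if (weight_decay > 0 && !is.null(dim(l$params[[nm]])))
        g <- g + weight_decay * l$params[[nm]]
      v <- l$opt[[nm]]
      v <- if (is.null(v)) g else momentum * v + g
      l$opt[[nm]] <- v
      l$params[[nm]] <- l$params[[nm]] - lr * v
    }
  }
  for (l in model$layers) walk_layers(l, step_layer)
  invisible(NULL)
}

# flat named tensor list for checkpoints / profiling
collect_tensors <- function(model) {
  out <- list()
  for (k in seq_along(model$layers)) {
    idx <- model$rows[[k]]$i
    walk_layers(model$layers[[k]], function(l, path) {
      for (nm in names(l$params))
        out[[paste0(idx, path, ".", nm)]] <<- list(v = l$params[[nm]],
                                                   kind = "param")
      for (nm in names(l$buffers))
        out[[paste0(idx, path, ".buf.", nm)]] <<- list(v = l$buffers[[nm]],
                                                       kind = "buffer")
    }, path = "")
  }
  out
}

assign_tensors <- function(model, values) {
  for (k in seq_along(model$layers)) {
    idx <- model$rows[[k]]$i
    walk_layers(model$layers[[k]], function(l, path) {
      for (nm in names(l$params)) {
        key <- paste0(idx, path, ".", nm)
        if (is.null(values[[key]])) stop("checkpoint missing tensor ", key)
        v <- values[[key]]
        dim(v) <- dim(l$params[[nm]])
        l$params[[nm]] <- v
      }
      for (nm in names(l$buffers)) {
        key <- paste0(idx, path, ".buf.", nm)
        if (!is.null(values[[key]])) {
          v <- values[[key]]
          dim(v) <- dim(l$buffers[[nm]])
          l$buffers[[nm]] <- v
        }
      }
    }, path = "")
  }
  invisible(model)
}

#' Save a model checkpoint
#'
#' Single-file binary container: a JSON header (configuration, tensor index,
#' numbering map) followed by the raw tensor payload at the requested
#' precision. `"double"` round-trips bit-exactly; `"half"` is the storage
#' convention the size metric is defined on.
#'
#' @param model a `bcsy_model`.
#' @param path output file.
#' @param precision `"double"`, `"single"`, or `"half"`.
#' @return the path, invisibly.
#' @export
save_checkpoint <- function(model, path, precision = c("double", "single",
                                                       "half")) {
  precision <- match.arg(precision)
  tensors <- collect_tensors(model)
  index <- lapply(names(tensors), function(nm) {
    v <- tensors[[nm]]$v
    list(name = nm, shape = if (is.null(dim(v))) length(v) else dim(v),
         kind = tensors[[nm]]$kind, n = length(v))
  })
  header <- jsonlite::toJSON(list(format = "bcsy-ckpt-1",
                                  precision = precision,
                                  config = unclass(model$cfg),
                                  numbering = vapply(model$rows,
                                                     function(r) r$i,
                                                     integer(1L)),
                                  tensors = index),
                             auto_unbox = TRUE, digits = NA)
  hraw <- charToRaw(as.character(header))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BCSY1"), con)
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  for (nm in names(tensors)) {
    v <- as.numeric(tensors[[nm]]$v)
    switch(precision,
           double = writeBin(v, con, size = 8L, endian = "little"),
           single = writeBin(v, con, size = 4L, endian = "little"),
           half = writeBin(cpp_fp16_pack(v), con))
  }
  invisible(path)
}

#' Load a model checkpoint
#'
#' Rebuilds the architecture from the stored configuration and restores all
#' tensors.
#'
#' @param path checkpoint file written by [save_checkpoint()].
#' @return a `bcsy_model`.
#' @export
load_checkpoint <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 5L))
  if (magic != "BCSY1") stop("not a bcsy checkpoint: ", path)
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)),
                               simplifyDataFrame = FALSE)
  cfgl <- header$config
  cfg <- model_config(cfgl$scale, cfgl$num_classes, cfgl$block_variant,
                      cfgl$head_variant, cfgl$input_size, cfgl$opts)
  model <- build_model(cfg)
  values <- list()
  for (tinfo in header$tensors) {
    n <- tinfo$n
    v <- switch(header$precision,
                double = readBin(con, "numeric", n, size = 8L,
                                 endian = "little"),
                single = readBin(con, "numeric", n, size = 4L,
                                 endian = "little"),
                half = cpp_fp16_unpack(readBin(con, "raw", 2L * n)))
    values[[tinfo$name]] <- v
  }
  assign_tensors(model, values)
  model
}

#' @export
print.bcsy_model <- function(x, ...) {
  cat(sprintf("<bcsy_model> %s-scale, blocks=%s, head=%s, %d classes\n",
              x$cfg$scale, x$cfg$block_variant, x$cfg$head_variant,
              x$cfg$num_classes))
  cat(sprintf("  %d top-level modules, %s learnable parameters\n",
              length(x$rows), format(count_params(x), big.mark = ",")))
  invisible(x)
}
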