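# Architecture profiling --------------------------------------------------
#
# FLOP convention: one multiply-accumulate = 2 FLOPs, counted for
# convolutions, linear maps, and the attention module's cross-spatial matrix
# products only. Normalization, activation, pooling and elementwise terms
# are treated as fused/free. This is the convention under which the n-scale
# baseline profiles at ~8.1 GFLOPs for a 640x640 input with 5 classes.
# Sizes are reported in MiB (2^20 bytes) of the half-precision checkpoint.

#' Count learnable parameters
#'
#' @param model a `bcsy_model` or any layer object.
#' @return integer count of learnable scalars (buffers excluded).
#' @export
count_params <- function(model) {
  total <- 0
  addl <- function(l, p) {
    for (nm in names(l$params)) total <<- total + length(l$params[[nm]])
  }
  if (inherits(model, "bcsy_model")) {
    for (l in model$layers) walk_layers(l, addl)
  } else if (inherits(model, "bcsy_layer")) {
    walk_layers(model, addl)
  } else stop("not a model or layer")
  total
}

# scalars that end up in a checkpoint (params + buffers)
count_saved_scalars <- function(model) {
  total <- 0
  addl <- function(l, p) {
    for (nm in names(l$params)) total <<- total + length(l$params[[nm]])
    for (nm in names(l$buffers)) total <<- total + length(l$buffers[[nm]])
  }
  for (l in model$layers) walk_layers(l, addl)
  total
}

conv_flops <- function(cin, cout, k, h, w, stride = 1L, groups = 1L) {
  p <- same_pad(k)
  ho <- (h + 2 * p - k) %/% stride + 1L
  wo <- (w + 2 * p - k) %/% stride + 1L
  2 * k * k * (cin / groups) * cout * ho * wo
}

# analytic per-layer FLOPs at spatial size (h, w); returns flops and the
# output spatial dims
flops_layer <- function(l, h, w) {
  f <- switch(l$kind,
    conv_unit = conv_flops(l$cin, l$cout, l$k, h, w, l$stride, l$groups),
    bottleneck = {
      ch <- l$children
      flops_layer(ch$cv1, h, w)$f + flops_layer(ch$cv2, h, w)$f
    },
    star_block = {
      ch <- l$children
      flops_layer(ch$dw1, h, w)$f + flops_layer(ch$f1, h, w)$f +
        flops_layer(ch$f2, h, w)$f + flops_layer(ch$g, h, w)$f +
        flops_layer(ch$dw2, h, w)$f
    },
    ema = {
      cg <- l$cg; G <- l$G
      f0 <- 2 * cg * cg * (h + w) * G            # shared 1x1 on pooled strip
      if (l$variant == "full_cited")
        f0 <- f0 + 2 * 9 * cg * cg * h * w * G + # per-group 3x3 branch
              2 * 2 * cg * h * w * G             # two cross-spatial matmuls
      f0
    },
    c2f = {
      ch <- l$children
      f0 <- flops_layer(ch$cv1, h, w)$f + flops_layer(ch$cv2, h, w)$f
      for (i in seq_len(l$n))
        f0 <- f0 + flops_layer(ch[[paste0("m", i)]], h, w)$f
      if (!is.null(ch$ema)) f0 <- f0 + flops_layer(ch$ema, h, w)$f
      f0
    },
    sppf = flops_layer(l$children$cv1, h, w)$f +
           flops_layer(l$children$cv2, h, w)$f,
    upsample = 0,
    concat = 0,
    detect_base = 0,   # handled by the model walker (multi-level input)
    ssldh = 0,
    stop("flops_layer: unsupported layer kind '", l$kind, "'"))
  s <- if (l$kind == "conv_unit") l$stride else 1L
  list(f = f, h = h %/% s, w = w %/% s)
}

head_flops <- function(l, hws) {
  f <- 0
  if (l$kind == "detect_base") {
    for (i in 1:3) {
      hw <- hws[[i]]
      for (stem in c("r", "c"))
        for (j in 1:3) {
          cu <- l$children[[paste0(stem, j, "_", i)]]
          f <- f + conv_flops(cu$cin, cu$cout, cu$k, hw[1], hw[2])
        }
    }
  } else if (l$kind == "ssldh") {
    for (i in 1:3) {
      hw <- hws[[i]]
      ad <- l$children[[paste0("ad_", i)]]
      f <- f + conv_flops(ad$cin, ad$cout, ad$k, hw[1], hw[2])
      for (nm in c("s1", "f1", "f2", "s2")) {
        cu <- l$children[[nm]]
        f <- f + conv_flops(cu$cin, cu$cout, cu$k, hw[1], hw[2])
      }
      for (kind in c("reg", "cls")) {
        cu <- ssldh_out(l, kind, i)
        f <- f + conv_flops(cu$cin, cu$cout, cu$k, hw[1], hw[2])
      }
    }
  } else stop("unknown head kind")
  f
}

#' Count FLOPs for one forward pass (analytic)
#'
#' Walks the graph and sums multiply-accumulate counts (x2) for all
#' convolution, linear, and attention matrix-product operations at the given
#' input size. Pure: no forward pass is executed.
#'
#' @param model a `bcsy_model`.
#' @param input_size square input resolution (divisible by 32).
#' @return FLOP count (double).
#' @export
count_flops <- function(model, input_size = model$cfg$input_size) {
  if (input_size %% 32L != 0L) stop("input_size must be divisible by 32")
  hw <- vector("list", length(model$rows))
  cur <- c(input_size, input_size)
  total <- 0
  for (k in seq_along(model$rows)) {
    r <- model$rows[[k]]
    inhw <- if (identical(r$from, -1L)) cur else hw[[r$from[1L] + 1L]]
    if (r$type == "head") {
      lv <- lapply(r$from, function(j) hw[[j + 1L]])
      total <- total + head_flops(model$layers[[k]], lv)
      hw[[k]] <- inhw
    } else if (r$type == "upsample") {
      hw[[k]] <- inhw * 2L
    } else if (r$type == "concat") {
      hw[[k]] <- inhw
    } else {
      fl <- flops_layer(model$layers[[k]], inhw[1L], inhw[2L])
      total <- total + fl$f
      hw[[k]] <- c(fl$h, fl$w)
    }
    cur <- hw[[k]]
  }
  total
}

# Runtime hook counter: counts the same convention from the shapes actually
# seen during an executed forward pass (cross-check for the analytic walker).
.prof <- new.env(parent = emptyenv())
.prof$active <- FALSE
.prof$flops <- 0

prof_add <- function(f) {
  if (isTRUE(.prof$active)) .prof$flops <- .prof$flops + f
  invisible(NULL)
}

#' Count FLOPs by executing a forward pass with counting hooks
#'
#' Independent cross-check of [count_flops()]: every convolution and matrix
#' product logs its multiply-accumulate count from the runtime shapes.
#' Reported per image (counts divided by the batch size).
#'
#' @param model a `bcsy_model`.
#' @param input_size square input resolution.
#' @return FLOP count (double).
#' @export
count_flops_measured <- function(model, input_size = model$cfg$input_size) {
  x <- array(0, c(1L, 3L, input_size, input_size))
  .prof$active <- TRUE
  .prof$flops <- 0
  on.exit(.prof$active <- FALSE)
  forward_model(model, x, training = FALSE)
  .prof$flops
}

#' Serialized checkpoint size
#'
#' Saves the model at the stated precision to a scratch file and measures it.
#'
#' @param model a `bcsy_model`.
#' @param precision `"half"` or `"single"`.
#' @return size in bytes.
#' @export
serialized_size <- function(model, precision = c("half", "single")) {
  precision <- match.arg(precision)
  tmp <- tempfile(fileext = ".bcsy")
  on.exit(unlink(tmp))
  save_checkpoint(model, tmp, precision = precision)
  file.size(tmp)
}

#' Profile a model
#'
#' @param model a `bcsy_model` (or a `bcsy_config`, which is built first;
#'   weight initialization does not affect any reported number).
#' @param input_size square input resolution for the FLOP count.
#' @return a `bcsy_profile` list: `param_count`, `flops`, `gflops`,
#'   `serialized_size_bytes` (half precision), `size_mb` (MiB).
#' @export
profile_model <- function(model, input_size = 640L) {
  if (inherits(model, "bcsy_config")) model <- build_model(model)
  fl <- count_flops(model, input_size)
  sz <- serialized_size(model, "half")
  structure(list(param_count = count_params(model),
                 flops = fl, gflops = fl / 1e9,
                 serialized_size_bytes = sz, size_mb = sz / 2^20,
                 input_size = input_size),
            class = "bcsy_profile")
}

#' @export
print.bcsy_profile <- function(x, ...) {
  cat(sprintf("params %s | %.1f GFLOPs @ %d | %.2f MB (fp16)\n",
              format(x$param_count, big.mark = ","), x$gflops, x$input_size,
              x$size_mb))
  invisible(x)
}

#' Table of profiles for the standard ablation variants
#'
#' Builds and profiles the named variants at n-scale (plus the s-scale
#' teacher) and returns one row per variant.
#'
#' @param variants character vector of [variant_config()] names.
#' @param num_classes,input_size forwarded to the configs.
#' @return data.frame with size/GFLOP columns.
#' @export
profile_table <- function(variants = c("baseline", "star", "star-ema", "bcs",
                                       "teacher"),
                          num_classes = 5L, input_size = 640L) {
  rows <- lapply(variants, function(v) {
    p <- profile_model(build_model(variant_config(v, num_classes)), input_size)
    data.frame(variant = v, params = p$param_count,
               gflops = round(p$gflops, 2), size_mb = round(p$size_mb, 2))
  })
  do.call(rbind, rows)
}
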