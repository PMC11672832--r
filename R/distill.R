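# Channel-wise knowledge distillation (CWD) -------------------------------
#
# Each channel's activation map is softmax-normalized over its spatial
# positions into a probability map; the distillation loss is the
# KL-divergence between teacher and student probability maps, summed over
# channels, scaled by T^2 / C. Gradients flow to the student only.

#' Per-channel spatial softmax
#'
#' `probs(c, i, j) = exp(x(c,i,j)/T) / sum_{i',j'} exp(x(c,i',j')/T)`,
#' numerically stabilized by max-subtraction.
#'
#' @param x feature map, `c(C, H, W)` or `c(N, C, H, W)`.
#' @param temperature softmax temperature, > 0.
#' @return a `channel_prob_map`: list with `probs` (same shape as `x`; each
#'   channel sums to 1 over the spatial positions) and `temperature`.
#' @export
channel_softmax <- function(x, temperature = 1) {
  if (!is.numeric(temperature) || length(temperature) != 1L || temperature <= 0)
    stop("temperature must be a positive number")
  nm <- as_nchw(x)
  p <- channel_softmax_raw(nm$x, temperature)
  structure(list(probs = un_nchw(p, nm$batched), temperature = temperature),
            class = "channel_prob_map")
}

# internal: batched array in, probability array out
channel_softmax_raw <- function(x, temperature) {
  d <- dim(x)
  m <- matrix(aperm(x, c(3L, 4L, 1L, 2L)), d[3L] * d[4L], d[1L] * d[2L])
  m <- m / temperature
  m <- sweep(m, 2L, apply(m, 2L, max))
  e <- exp(m)
  p <- sweep(e, 2L, colSums(e), "/")
  aperm(array(p, c(d[3L], d[4L], d[1L], d[2L])), c(3L, 4L, 1L, 2L))
}

#' Channel-wise distillation loss
#'
#' `(T^2 / C) * sum_c KL(phi_T(teacher)_c || phi_T(student)_c)` where
#' `phi_T` is the per-channel spatial softmax at temperature T; averaged
#' over the batch when a batch dimension is present. The teacher is treated
#' as a constant.
#'
#' @param teacher_fm,student_fm feature maps of identical shape.
#' @param temperature softmax temperature, > 0.
#' @return non-negative scalar.
#' @export
cwd_loss <- function(teacher_fm, student_fm, temperature = 4) {
  cwd_loss_grad(teacher_fm, student_fm, temperature, want_grad = FALSE)$loss
}

cwd_loss_grad <- function(teacher_fm, student_fm, temperature,
                          want_grad = TRUE) {
  if (!is.numeric(temperature) || temperature <= 0)
    stop("temperature must be positive")
  tn <- as_nchw(teacher_fm); sn <- as_nchw(student_fm)
  if (!identical(dim(tn$x), dim(sn$x)))
    stop("teacher/student shape mismatch after adaptation: ",
         paste(dim(tn$x), collapse = "x"), " vs ",
         paste(dim(sn$x), collapse = "x"))
  d <- dim(tn$x); N <- d[1L]; C <- d[2L]
  pt <- channel_softmax_raw(tn$x, temperature)
  ps <- channel_softmax_raw(sn$x, temperature)
  eps <- 1e-12
  kl <- sum(pt * (log(pt + eps) - log(ps + eps)))
  loss <- temperature^2 / C * kl / N
  out <- list(loss = max(0, loss))
  if (want_grad) {
    g <- temperature / (C * N) * (ps - pt)
    out$dstudent <- un_nchw(g, sn$batched)
  }
  out
}

#' 1x1 channel adapter parameters
#'
#' Learnable linear map used to match a student feature map's width to the
#' teacher's at a distillation site. Identity-initialized when the widths
#' already agree.
#'
#' @param in_channels,target_channels widths.
#' @return a conv unit layer.
#' @export
adapter_params <- function(in_channels, target_channels) {
  l <- conv_unit(as.integer(in_channels), as.integer(target_channels), 1L,
                 norm = "none", act = "none")
  if (in_channels == target_channels) {
    w <- array(0, c(target_channels, in_channels, 1L, 1L))
    for (i in seq_len(in_channels)) w[i, i, 1L, 1L] <- 1
    l$params$w <- w
    l$params$b <- rep(0, target_channels)
  }
  l
}

#' Adapt a student feature map to a target channel width
#'
#' @param student_fm feature map.
#' @param target_channels desired channel count.
#' @param adapter_weights parameters from [adapter_params()].
#' @return feature map with `target_channels` channels, same spatial dims.
#' @export
adapt_channels <- function(student_fm, target_channels, adapter_weights) {
  if (adapter_weights$cout != target_channels)
    stop("adapter produces ", adapter_weights$cout, " channels, wanted ",
         target_channels)
  nm <- as_nchw(student_fm)
  un_nchw(ly_fwd(adapter_weights, nm$x, training = FALSE), nm$batched)
}

#' Distillation configuration
#'
#' @param layer_pairs list of `c(teacher_index, student_index)` pairs in the
#'   canonical graph numbering; defaults to the four neck fusion outputs
#'   (12, 15, 18, 21) on both sides.
#' @param temperature softmax temperature (default 4).
#' @param loss_weight weight of the distillation term in the total loss.
#' @param weight_schedule only `"constant"` is supported.
#' @param loss_type only `"feature"` (feature-map distillation) is exercised;
#'   `"logits"` is accepted but applies the same mechanism to head outputs.
#' @param lr learning rate of the student updates inside [distill_step()].
#' @param momentum SGD momentum of those updates.
#' @return a `bcsy_distill_config` environment (holds the adapters).
#' @export
distill_config <- function(layer_pairs = list(c(12L, 12L), c(15L, 15L),
                                              c(18L, 18L), c(21L, 21L)),
                           temperature = 4, loss_weight = 1,
                           weight_schedule = "constant",
                           loss_type = "feature", lr = 0.01,
                           momentum = 0.9) {
  if (temperature <= 0) stop("temperature must be > 0")
  if (!identical(weight_schedule, "constant"))
    stop("only the constant weight schedule is supported")
  for (p in layer_pairs)
    if (any(p < 0L) || any(p > 22L))
      stop("layer index out of range in pair (", paste(p, collapse = ", "), ")")
  e <- new.env(parent = emptyenv())
  e$layer_pairs <- layer_pairs
  e$temperature <- temperature
  e$loss_weight <- loss_weight
  e$weight_schedule <- weight_schedule
  e$loss_type <- loss_type
  e$lr <- lr
  e$momentum <- momentum
  e$adapters <- list()
  class(e) <- "bcsy_distill_config"
  e
}

#' One distillation training step
#'
#' Runs the frozen teacher and the student on a batch, computes the
#' detection loss plus the weighted sum of CWD losses at the registered
#' layer pairs (student maps passed through their 1x1 adapters), backprops
#' through the student and adapters, and applies one SGD update.
#'
#' @param batch list with `x` (image batch, `c(N,3,H,W)`) and `targets`
#'   (per-image matrices of `cbind(class, x1, y1, x2, y2)` in pixels).
#' @param teacher_model frozen teacher (`bcsy_model`).
#' @param student_model student (`bcsy_model`), updated in place.
#' @param cfg a [distill_config()].
#' @param update logical; apply the SGD step (default TRUE).
#' @return list with `detection`, `distill`, and `total` loss values.
#' @export
distill_step <- function(batch, teacher_model, student_model, cfg,
                         update = TRUE) {
  stopifnot(inherits(cfg, "bcsy_distill_config"))
  x <- batch$x
  forward_model(teacher_model, x, training = FALSE)
  tout <- teacher_model$outs
  forward_model(student_model, x, training = TRUE)
  sout <- student_model$outs
  det <- detection_loss(student_model$head_out, batch$targets,
                        student_model$strides,
                        student_model$cfg$opts$reg_max,
                        student_model$cfg$num_classes,
                        img_size = dim(x)[3:4])
  extra <- list()
  dl <- 0
  if (identical(cfg$loss_type, "logits")) {
    # logits-mode: channel softmax KL directly on the per-level class maps
    for (i in 1:3) {
      r <- cwd_loss_grad(teacher_model$head_out$cls[[i]],
                         student_model$head_out$cls[[i]], cfg$temperature)
      dl <- dl + r$loss
      det$dhead$cls[[i]] <- det$dhead$cls[[i]] + cfg$loss_weight * r$dstudent
    }
  } else for (k in seq_along(cfg$layer_pairs)) {
    pr <- cfg$layer_pairs[[k]]
    t_fm <- tout[[as.character(pr[1L])]]
    s_fm <- sout[[as.character(pr[2L])]]
    if (is.null(t_fm) || is.null(s_fm))
      stop("no hookable feature map at layer pair (",
           paste(pr, collapse = ", "), ")")
    key <- paste(pr, collapse = "_")
    if (is.null(cfg$adapters[[key]]))
      cfg$adapters[[key]] <- adapter_params(dim(s_fm)[2L], dim(t_fm)[2L])
    ad <- cfg$adapters[[key]]
    a_fm <- ly_fwd(ad, s_fm, training = TRUE)
    r <- cwd_loss_grad(t_fm, a_fm, cfg$temperature)
    dl <- dl + r$loss
    ds <- ly_bwd(ad, cfg$loss_weight * r$dstudent)
    nmk <- as.character(pr[2L])
    extra[[nmk]] <- if (is.null(extra[[nmk]])) ds else extra[[nmk]] + ds
  }
  zero_grads(student_model)
  backward_model(student_model, det$dhead, extra_grads = extra)
  if (update) {
    sgd_step(student_model, cfg$lr, cfg$momentum)
    for (key in names(cfg$adapters)) {
      ad <- cfg$adapters[[key]]
      for (nm in names(ad$params)) {
        g <- ad$grads[[nm]]
        if (is.null(g)) next
        v <- ad$opt[[nm]] %||% (g * 0)
        v <- cfg$momentum * v + g
        ad$opt[[nm]] <- v
        ad$params[[nm]] <- ad$params[[nm]] - cfg$lr * v
      }
      ad$grads <- list()
    }
  }
  clear_caches(student_model)
  list(detection = det$total, distill = dl,
       total = det$total + cfg$loss_weight * dl)
}
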