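# Training ----------------------------------------------------------------

#' Training configuration
#'
#' Defaults follow the study conditions: 100 epochs, batch 16, SGD with
#' initial learning rate 0.01 (decayed linearly to `lr0 * lrf`), 640 input,
#' HSV gains 0.015/0.7/0.4, translate 0.1, scale 0.5, both flips at 0.5,
#' NMS IoU 0.7. `workers` is recorded for API compatibility; execution is
#' single-process.
#'
#' @param epochs,batch_size,workers,input_size training schedule.
#' @param lr0 initial learning rate; `lrf` final fraction.
#' @param momentum,weight_decay SGD settings.
#' @param augment list of augmentation gains (`hsv_h`, `hsv_s`, `hsv_v`,
#'   `degrees`, `translate`, `scale`, `shear`, `flipud`, `fliplr`).
#' @param nms_iou NMS threshold used at validation time.
#' @param seed RNG seed for shuffling, augmentation and initialization.
#' @return a `bcsy_train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 16L, workers = 4L,
                         input_size = 640L, lr0 = 0.01, lrf = 0.01,
                         momentum = 0.937, weight_decay = 5e-4,
                         augment = list(hsv_h = 0.015, hsv_s = 0.7,
                                        hsv_v = 0.4, degrees = 0,
                                        translate = 0.1, scale = 0.5,
                                        shear = 0, flipud = 0.5,
                                        fliplr = 0.5),
                         nms_iou = 0.7, seed = 0L) {
  pr <- c(augment$flipud, augment$fliplr)
  if (any(pr < 0 | pr > 1)) stop("flip probabilities must be in [0, 1]")
  if (nms_iou <= 0 || nms_iou >= 1) stop("nms_iou must be in (0, 1)")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 workers = as.integer(workers),
                 input_size = as.integer(input_size),
                 lr0 = lr0, lrf = lrf, momentum = momentum,
                 weight_decay = weight_decay, augment = augment,
                 nms_iou = nms_iou, seed = as.integer(seed)),
            class = "bcsy_train_config")
}

# bilinear resize of a (C, H, W) image
resize_bilinear <- function(img, oh, ow) {
  d <- dim(img)
  H <- d[2L]; W <- d[3L]
  ys <- (seq_len(oh) - 0.5) * H / oh + 0.5
  xs <- (seq_len(ow) - 0.5) * W / ow + 0.5
  y0 <- pmin(pmax(floor(ys), 1L), H); y1 <- pmin(y0 + 1L, H)
  x0 <- pmin(pmax(floor(xs), 1L), W); x1 <- pmin(x0 + 1L, W)
  fy <- pmin(pmax(ys - y0, 0), 1); fx <- pmin(pmax(xs - x0, 0), 1)
  out <- array(0, c(d[1L], oh, ow))
  for (c in seq_len(d[1L])) {
    a <- img[c, , ]
    top <- a[y0, x0, drop = FALSE] * (1 - fx)[col(matrix(0, oh, ow))] +
           a[y0, x1, drop = FALSE] * fx[col(matrix(0, oh, ow))]
    bot <- a[y1, x0, drop = FALSE] * (1 - fx)[col(matrix(0, oh, ow))] +
           a[y1, x1, drop = FALSE] * fx[col(matrix(0, oh, ow))]
    out[c, , ] <- top * (1 - fy) + bot * fy
  }
  out
}

#' Letterbox an image to a square network input
#'
#' Aspect-preserving bilinear resize, centered on a gray canvas.
#'
#' @param img `c(3, H, W)` array in `[0, 1]`.
#' @param size target square size.
#' @param fill padding value (default 114/255, the conventional gray).
#' @return list: `img` (`c(3, size, size)`), `ratio`, `pad = c(px, py)` —
#'   the transform needed to map normalized source boxes.
#' @export
letterbox_image <- function(img, size, fill = 114 / 255) {
  d <- dim(img)
  r <- min(size / d[2L], size / d[3L])
  nh <- max(1L, round(d[2L] * r)); nw <- max(1L, round(d[3L] * r))
  rs <- resize_bilinear(img, nh, nw)
  out <- array(fill, c(d[1L], size, size))
  py <- (size - nh) %/% 2L; px <- (size - nw) %/% 2L
  out[, py + seq_len(nh), px + seq_len(nw)] <- rs
  list(img = out, ratio = r, pad = c(px, py), src = c(d[3L], d[2L]))
}

# map normalized (cx,cy,w,h) boxes through a letterbox transform into pixel
# (cx,cy,w,h) on the canvas
letterbox_boxes <- function(boxes, lb, size) {
  if (is.null(boxes) || nrow(boxes) == 0L) return(boxes)
  sw <- lb$src[1L]; sh <- lb$src[2L]
  cbind(boxes[, 1L],
        boxes[, 2L] * sw * lb$ratio + lb$pad[1L],
        boxes[, 3L] * sh * lb$ratio + lb$pad[2L],
        boxes[, 4L] * sw * lb$ratio,
        boxes[, 5L] * sh * lb$ratio)
}

hsv_to_rgb <- function(h, s, v) {
  i <- floor(h * 6) %% 6
  f <- h * 6 - floor(h * 6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  rbind(r, g, b)
}

#' Augment one training sample
#'
#' HSV jitter at the configured gains, random scale (factor in
#' `1 +/- scale`), random translation (`+/- translate` of the image size),
#' and horizontal/vertical flips at their configured probabilities. Boxes
#' are transformed consistently, clipped, and dropped when degenerate.
#' Deterministic for a fixed RNG state (or pass `rng` to seed locally).
#'
#' @param img `c(3, H, W)` array in `[0, 1]`.
#' @param boxes normalized label matrix `cbind(class, cx, cy, w, h)`.
#' @param aug augmentation gain list (see [train_config()]).
#' @param rng optional integer seed applied locally (session RNG restored).
#' @return list with transformed `img` and `boxes`.
#' @export
augment_sample <- function(img, boxes, aug, rng = NULL) {
  if (!is.null(rng)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(rng)
  }
  d <- dim(img); H <- d[2L]; W <- d[3L]
  # HSV jitter (multiplicative on s/v, additive wrap on h)
  if (any(unlist(aug[c("hsv_h", "hsv_s", "hsv_v")]) > 0)) {
    gains <- stats::runif(3, -1, 1) * c(aug$hsv_h, aug$hsv_s, aug$hsv_v)
    m <- matrix(img, 3L, H * W)
    hsv <- grDevices::rgb2hsv(m[1L, ], m[2L, ], m[3L, ], maxColorValue = 1)
    h <- (hsv[1L, ] + gains[1L]) %% 1
    s <- pmin(pmax(hsv[2L, ] * (1 + gains[2L]), 0), 1)
    v <- pmin(pmax(hsv[3L, ] * (1 + gains[3L]), 0), 1)
    img <- array(hsv_to_rgb(h, s, v), c(3L, H, W))
  }
  # scale + translate (nearest sampling, gray fill)
  sf <- 1 + stats::runif(1, -1, 1) * (aug$scale %||% 0)
  tx <- stats::runif(1, -1, 1) * (aug$translate %||% 0) * W
  ty <- stats::runif(1, -1, 1) * (aug$translate %||% 0) * H
  if (sf != 1 || tx != 0 || ty != 0) {
    cx0 <- (W + 1) / 2; cy0 <- (H + 1) / 2
    xs <- round((seq_len(W) - cx0 - tx) / sf + cx0)
    ys <- round((seq_len(H) - cy0 - ty) / sf + cy0)
    okx <- xs >= 1L & xs <= W; oky <- ys >= 1L & ys <= H
    new <- array(114 / 255, dim(img))
    new[, which(oky), which(okx)] <- img[, ys[oky], xs[okx], drop = FALSE]
    img <- new
    if (!is.null(boxes) && nrow(boxes) > 0L) {
      px <- (boxes[, 2L] * W - cx0) * sf + cx0 + tx
      py <- (boxes[, 3L] * H - cy0) * sf + cy0 + ty
      boxes[, 2L] <- px / W; boxes[, 3L] <- py / H
      boxes[, 4L] <- boxes[, 4L] * sf; boxes[, 5L] <- boxes[, 5L] * sf
    }
  }
  if (stats::runif(1) < (aug$fliplr %||% 0)) {
    img <- img[, , W:1, drop = FALSE]
    if (!is.null(boxes) && nrow(boxes) > 0L) boxes[, 2L] <- 1 - boxes[, 2L]
  }
  if (stats::runif(1) < (aug$flipud %||% 0)) {
    img <- img[, H:1, , drop = FALSE]
    if (!is.null(boxes) && nrow(boxes) > 0L) boxes[, 3L] <- 1 - boxes[, 3L]
  }
  # clip to the image, drop degenerate boxes
  if (!is.null(boxes) && nrow(boxes) > 0L) {
    x1 <- pmin(pmax(boxes[, 2L] - boxes[, 4L] / 2, 0), 1)
    x2 <- pmin(pmax(boxes[, 2L] + boxes[, 4L] / 2, 0), 1)
    y1 <- pmin(pmax(boxes[, 3L] - boxes[, 5L] / 2, 0), 1)
    y2 <- pmin(pmax(boxes[, 3L] + boxes[, 5L] / 2, 0), 1)
    keep <- (x2 - x1) * W > 2 & (y2 - y1) * H > 2
    boxes <- cbind(boxes[, 1L], (x1 + x2) / 2, (y1 + y2) / 2,
                   x2 - x1, y2 - y1)[keep, , drop = FALSE]
  }
  list(img = img, boxes = boxes)
}

# normalized (class,cx,cy,w,h) at size S -> pixel (class,x1,y1,x2,y2)
boxes_to_pixels <- function(boxes, S) {
  if (is.null(boxes) || nrow(boxes) == 0L)
    return(matrix(numeric(), 0L, 5L))
  cbind(boxes[, 1L],
        (boxes[, 2L] - boxes[, 4L] / 2) * S,
        (boxes[, 3L] - boxes[, 5L] / 2) * S,
        (boxes[, 2L] + boxes[, 4L] / 2) * S,
        (boxes[, 3L] + boxes[, 5L] / 2) * S)
}

#' Train a detector
#'
#' Standard single-process SGD training with the composite detection loss
#' (CIoU box + BCE class + distribution-focal). The learning rate decays
#' linearly from `lr0` at epoch 0 to `lr0 * lrf`.
#'
#' @param model a `bcsy_model`; updated in place.
#' @param samples list of training samples: `list(img = c(3,S,S) array,
#'   boxes_norm = normalized label matrix cbind(class, cx, cy, w, h))`, with
#'   S equal to `cfg$input_size` (see [load_dataset_samples()]).
#' @param cfg a [train_config()].
#' @param augment logical; apply the augmentation pipeline.
#' @param verbose print per-epoch losses.
#' @return data.frame log with per-epoch `box`, `cls`, `dfl`, `total`
#'   losses and the learning rate.
#' @export
train_model <- function(model, samples, cfg = train_config(),
                        augment = TRUE, verbose = FALSE) {
  if (length(samples) == 0L) stop("empty dataset")
  set.seed(cfg$seed)
  S <- cfg$input_size
  nlog <- list()
  for (ep in seq_len(cfg$epochs) - 1L) {
    lr <- cfg$lr0 * (1 - ep / cfg$epochs * (1 - cfg$lrf))
    ord <- sample(length(samples))
    ep_loss <- c(box = 0, cls = 0, dfl = 0, total = 0)
    nb <- 0
    for (b0 in seq(1L, length(ord), cfg$batch_size)) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1L, length(ord))]
      imgs <- vector("list", length(idx))
      tgts <- vector("list", length(idx))
      for (j in seq_along(idx)) {
        sm <- samples[[idx[j]]]
        if (augment) {
          a <- augment_sample(sm$img, sm$boxes_norm, cfg$augment)
          imgs[[j]] <- a$img
          tgts[[j]] <- boxes_to_pixels(a$boxes, S)
        } else {
          imgs[[j]] <- sm$img
          tgts[[j]] <- boxes_to_pixels(sm$boxes_norm, S)
        }
      }
      x <- array(0, c(length(idx), 3L, S, S))
      for (j in seq_along(idx)) x[j, , , ] <- imgs[[j]]
      raw <- forward_model(model, x, training = TRUE)
      ls <- detection_loss(raw, tgts, model$strides, model$cfg$opts$reg_max,
                           model$cfg$num_classes, c(S, S))
      if (!is.finite(ls$total)) stop("non-finite loss at epoch ", ep)
      zero_grads(model)
      backward_model(model, ls$dhead)
      sgd_step(model, lr, cfg$momentum, cfg$weight_decay)
      clear_caches(model)
      ep_loss <- ep_loss + c(ls$box, ls$cls, ls$dfl, ls$total)
      nb <- nb + 1
    }
    ep_loss <- ep_loss / nb
    nlog[[ep + 1L]] <- data.frame(epoch = ep, lr = lr,
                                  box = ep_loss[1L], cls = ep_loss[2L],
                                  dfl = ep_loss[3L], total = ep_loss[4L])
    if (verbose)
      message(sprintf("epoch %d lr %.4f box %.3f cls %.3f dfl %.3f total %.3f",
                      ep, lr, ep_loss[1L], ep_loss[2L], ep_loss[3L],
                      ep_loss[4L]))
  }
  do.call(rbind, nlog)
}

#' Predict detections on one image
#'
#' @param model a `bcsy_model`.
#' @param img `c(3, H, W)` array in `[0, 1]`, dims divisible by 32.
#' @param conf_threshold,nms_iou post-processing thresholds.
#' @return data.frame of detections (pixel xyxy).
#' @export
predict_detections <- function(model, img, conf_threshold = 0.25,
                               nms_iou = 0.7) {
  x <- img
  if (length(dim(x)) == 3L) dim(x) <- c(1L, dim(x))
  raw <- forward_model(model, x, training = FALSE)
  hcfg <- head_config(rep(1L, 3L), model$strides,
                      num_classes = model$cfg$num_classes,
                      reg_max = model$cfg$opts$reg_max, hidden_channels = 16L)
  dets <- decode_boxes(raw, hcfg, conf_threshold,
                       img_size = c(dim(x)[4L], dim(x)[3L]))
  nms(dets, nms_iou)
}
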