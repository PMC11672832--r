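# Detection metrics -------------------------------------------------------

# IoU between two box matrices (rows = boxes, cols = x1,y1,x2,y2)
box_iou_mat <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  out <- matrix(0, na, nb)
  for (i in seq_len(na)) {
    ix <- pmax(0, pmin(a[i, 3], b[, 3]) - pmax(a[i, 1], b[, 1]))
    iy <- pmax(0, pmin(a[i, 4], b[, 4]) - pmax(a[i, 2], b[, 2]))
    inter <- ix * iy
    ua <- (a[i, 3] - a[i, 1]) * (a[i, 4] - a[i, 2]) +
      (b[, 3] - b[, 1]) * (b[, 4] - b[, 2]) - inter
    out[i, ] <- inter / pmax(ua, 1e-12)
  }
  out
}

#' Non-maximum suppression
#'
#' Greedy per-class suppression by descending confidence; among surviving
#' same-class pairs the IoU never exceeds the threshold. Equal-confidence
#' ties are broken by ascending original index (stable).
#'
#' @param dets data.frame with `class_id`, `confidence`, `x1`, `y1`, `x2`,
#'   `y2` (as produced by [decode_boxes()]).
#' @param iou_threshold suppression threshold in (0, 1).
#' @return the surviving subset of `dets`.
#' @export
nms <- function(dets, iou_threshold = 0.7) {
  if (nrow(dets) == 0L) return(dets)
  keep_all <- integer()
  for (cl in unique(dets$class_id)) {
    idx <- which(dets$class_id == cl)
    ord <- idx[order(-dets$confidence[idx], idx)]
    boxes <- as.matrix(dets[ord, c("x1", "y1", "x2", "y2")])
    alive <- rep(TRUE, length(ord))
    for (i in seq_along(ord)) {
      if (!alive[i]) next
      keep_all <- c(keep_all, ord[i])
      if (i < length(ord)) {
        rest <- which(alive & seq_along(ord) > i)
        if (length(rest)) {
          iou <- box_iou_mat(boxes[i, , drop = FALSE],
                             boxes[rest, , drop = FALSE])[1L, ]
          alive[rest[iou > iou_threshold]] <- FALSE
        }
      }
    }
  }
  dets[sort(keep_all), , drop = FALSE]
}

#' Match detections to ground truth
#'
#' Greedy one-to-one matching per class at a fixed IoU threshold:
#' predictions in descending confidence order each claim the highest-IoU
#' unmatched truth of their class (IoU >= threshold), else count as false
#' positives; unmatched truths are false negatives.
#'
#' @param preds data.frame of detections, sorted or not (sorted internally
#'   by descending confidence).
#' @param truths matrix `cbind(class, x1, y1, x2, y2)`.
#' @param iou_threshold matching threshold.
#' @return list with `tp`, `fp`, `fn` counts and `flags` — per prediction
#'   (in descending-confidence order) TRUE for true positives — plus
#'   `order`, the row permutation applied to `preds`.
#' @export
match_detections <- function(preds, truths, iou_threshold = 0.5) {
  nt <- if (is.null(truths)) 0L else nrow(truths)
  if (nrow(preds) == 0L)
    return(list(tp = 0L, fp = 0L, fn = nt, flags = logical(), order = integer()))
  ord <- order(-preds$confidence, seq_len(nrow(preds)))
  p <- preds[ord, , drop = FALSE]
  used <- rep(FALSE, nt)
  flags <- logical(nrow(p))
  for (i in seq_len(nrow(p))) {
    if (nt == 0L) break
    same <- which(!used & truths[, 1L] == p$class_id[i])
    if (!length(same)) next
    iou <- box_iou_mat(as.matrix(p[i, c("x1", "y1", "x2", "y2")]),
                       truths[same, 2:5, drop = FALSE])[1L, ]
    j <- which.max(iou)
    if (iou[j] >= iou_threshold) {
      flags[i] <- TRUE
      used[same[j]] <- TRUE
    }
  }
  list(tp = sum(flags), fp = sum(!flags), fn = nt - sum(flags),
       flags = flags, order = ord)
}

#' Average precision from a precision-recall curve
#'
#' @param pr_points data.frame with `recall` and `precision` columns
#'   (one point per confidence cut, any order).
#' @param mode `"all_points"` (area under the precision envelope; default)
#'   or `"eleven_point"` (mean of envelope precision at recalls 0, 0.1, ...,
#'   1.0).
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(pr_points, mode = c("all_points",
                                                  "eleven_point")) {
  mode <- match.arg(mode)
  if (nrow(pr_points) == 0L) return(0)
  o <- order(pr_points$recall)
  r <- c(0, pr_points$recall[o], 1)
  p <- c(1, pr_points$precision[o], 0)
  # precision envelope: running max from the right
  for (i in (length(p) - 1L):1L) p[i] <- max(p[i], p[i + 1L])
  if (mode == "eleven_point") {
    rq <- seq(0, 1, 0.1)
    pe <- vapply(rq, function(q) {
      i <- which(r >= q)
      if (length(i)) p[min(i)] else 0
    }, numeric(1L))
    return(mean(pe))
  }
  sum(diff(r) * p[-1L])
}

# AP for one class from pooled flags
ap_from_flags <- function(conf, flags, n_truth, mode = "all_points") {
  if (n_truth == 0L) return(0)
  if (length(conf) == 0L) return(0)
  o <- order(-conf)
  tp <- cumsum(flags[o])
  fp <- cumsum(!flags[o])
  pr <- data.frame(recall = tp / n_truth, precision = tp / (tp + fp))
  average_precision(pr, mode)
}

#' Mean average precision over classes
#'
#' @param per_class_ap numeric vector of per-class AP values.
#' @return their arithmetic mean.
#' @export
map_over_classes <- function(per_class_ap) {
  if (length(per_class_ap) == 0L) stop("no classes to average over")
  mean(per_class_ap)
}

#' Evaluate a detector on a dataset
#'
#' Runs the model image by image, decodes and NMS-filters predictions, and
#' computes per-class precision/recall (at `conf_pr`), AP at IoU 0.5 and
#' averaged over IoU 0.50:0.05:0.95, plus their class means (mAP\@50,
#' mAP\@50:95).
#'
#' @param model a `bcsy_model`.
#' @param samples list of samples, each `list(img = c(3,H,W) array in
#'   [0,1], boxes_px = matrix cbind(class, x1, y1, x2, y2) in pixels)`.
#' @param conf_threshold decode threshold for the PR sweep (low, default
#'   0.001).
#' @param conf_pr operating-point threshold for the reported P/R.
#' @param nms_iou NMS threshold (default 0.7).
#' @param ap_mode AP interpolation mode, see [average_precision()].
#' @return a `bcsy_metrics` list: `per_class` data.frame, `mAP50`,
#'   `mAP50_95`, `precision`, `recall` (macro over classes with truths).
#' @export
evaluate_model <- function(model, samples, conf_threshold = 0.001,
                           conf_pr = 0.25, nms_iou = 0.7,
                           ap_mode = "all_points") {
  nc <- model$cfg$num_classes
  hcfg <- head_config(rep(1L, 3L), model$strides,
                      num_classes = nc, reg_max = model$cfg$opts$reg_max,
                      hidden_channels = 16L)
  iods <- seq(0.5, 0.95, 0.05)
  acc <- lapply(seq_len(nc), function(i)
    list(conf = numeric(), flags = matrix(logical(), 0, length(iods)),
         n_truth = 0L))
  for (s in samples) {
    x <- s$img
    if (length(dim(x)) == 3L) dim(x) <- c(1L, dim(x))
    raw <- forward_model(model, x, training = FALSE)
    dets <- decode_boxes(raw, hcfg, conf_threshold,
                         img_size = c(dim(x)[4L], dim(x)[3L]))
    dets <- nms(dets, nms_iou)
    for (cl in seq_len(nc) - 1L) {
      pcl <- dets[dets$class_id == cl, , drop = FALSE]
      tcl <- s$boxes_px[s$boxes_px[, 1L] == cl, , drop = FALSE]
      fl <- matrix(FALSE, nrow(pcl), length(iods))
      conf_sorted <- numeric(0)
      for (ti in seq_along(iods)) {
        m <- match_detections(pcl, tcl, iods[ti])
        fl[, ti] <- m$flags
        conf_sorted <- pcl$confidence[m$order]
      }
      a <- acc[[cl + 1L]]
      a$conf <- c(a$conf, conf_sorted)
      a$flags <- rbind(a$flags, fl)
      a$n_truth <- a$n_truth + nrow(tcl)
      acc[[cl + 1L]] <- a
    }
  }
  per <- data.frame(class_id = seq_len(nc) - 1L, P = NA_real_, R = NA_real_,
                    AP50 = NA_real_, AP50_95 = NA_real_)
  for (cl in seq_len(nc)) {
    a <- acc[[cl]]
    aps <- vapply(seq_along(iods), function(ti)
      ap_from_flags(a$conf, a$flags[, ti], a$n_truth, ap_mode), numeric(1L))
    per$AP50[cl] <- aps[1L]
    per$AP50_95[cl] <- mean(aps)
    sel <- a$conf >= conf_pr
    tp <- sum(a$flags[sel, 1L]); fp <- sum(sel) - tp
    per$P[cl] <- if (tp + fp > 0) tp / (tp + fp) else 0
    per$R[cl] <- if (a$n_truth > 0) tp / a$n_truth else NA_real_
  }
  with_truth <- vapply(acc, function(a) a$n_truth > 0L, logical(1L))
  structure(list(per_class = per,
                 mAP50 = map_over_classes(per$AP50[with_truth]),
                 mAP50_95 = map_over_classes(per$AP50_95[with_truth]),
                 precision = mean(per$P[with_truth]),
                 recall = mean(per$R[with_truth])),
            class = "bcsy_metrics")
}

#' @export
print.bcsy_metrics <- function(x, ...) {
  cat(sprintf("P %.3f  R %.3f  mAP@50 %.3f  mAP@50:95 %.3f\n",
              x$precision, x$recall, x$mAP50, x$mAP50_95))
  invisible(x)
}
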