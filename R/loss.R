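# Detection loss ----------------------------------------------------------
#
# Composite loss of the baseline lineage: CIoU on decoded boxes + binary
# cross-entropy on class logits + distribution-focal loss on the per-side
# bin distributions. Positive anchors: cell centers inside the ground-truth
# box, top-10 by center distance across the three levels (nearest anchor as
# fallback for degenerate boxes). Box-loss gradients w.r.t. the four decoded
# distances use central finite differences (the CIoU penalty terms are
# piecewise-smooth and O(1) per anchor), chained analytically through the
# softmax expectation onto the logits.

ciou <- function(b1, b2) {
  # b = c(x1, y1, x2, y2)
  w1 <- max(b1[3] - b1[1], 1e-9); h1 <- max(b1[4] - b1[2], 1e-9)
  w2 <- max(b2[3] - b2[1], 1e-9); h2 <- max(b2[4] - b2[2], 1e-9)
  ix <- max(0, min(b1[3], b2[3]) - max(b1[1], b2[1]))
  iy <- max(0, min(b1[4], b2[4]) - max(b1[2], b2[2]))
  inter <- ix * iy
  union <- w1 * h1 + w2 * h2 - inter
  iou <- inter / union
  cw <- max(b1[3], b2[3]) - min(b1[1], b2[1])
  ch <- max(b1[4], b2[4]) - min(b1[2], b2[2])
  c2 <- cw^2 + ch^2 + 1e-9
  rho2 <- ((b1[1] + b1[3] - b2[1] - b2[3])^2 +
           (b1[2] + b1[4] - b2[2] - b2[4])^2) / 4
  v <- (4 / pi^2) * (atan(w2 / h2) - atan(w1 / h1))^2
  alpha <- v / (v - iou + 1 + 1e-9)
  iou - rho2 / c2 - alpha * v
}

# positive anchors for one ground-truth box: indices into the flattened
# per-level grids plus their level
assign_anchors <- function(gt, grids, topk = 10L) {
  cand <- NULL
  for (lv in seq_along(grids)) {
    g <- grids[[lv]]
    inside <- g$cx > gt[1] & g$cx < gt[3] & g$cy > gt[2] & g$cy < gt[4]
    if (any(inside)) {
      ii <- which(inside)
      d <- (g$cx[ii] - (gt[1] + gt[3]) / 2)^2 + (g$cy[ii] - (gt[2] + gt[4]) / 2)^2
      cand <- rbind(cand, cbind(lv, ii, d))
    }
  }
  if (is.null(cand)) {     # degenerate/tiny box: nearest anchor overall
    best <- NULL
    for (lv in seq_along(grids)) {
      g <- grids[[lv]]
      d <- (g$cx - (gt[1] + gt[3]) / 2)^2 + (g$cy - (gt[2] + gt[4]) / 2)^2
      i <- which.min(d)
      best <- rbind(best, c(lv, i, d[i]))
    }
    cand <- best[which.min(best[, 3]), , drop = FALSE]
  }
  cand <- cand[order(cand[, 3]), , drop = FALSE]
  utils::head(cand, topk)[, 1:2, drop = FALSE]
}

detection_loss <- function(raw, targets, strides, reg_max, nc, img_size,
                           gains = list(box = 7.5, cls = 0.5, dfl = 1.5)) {
  R <- reg_max
  N <- dim(raw$cls[[1L]])[1L]
  grids <- lapply(seq_along(strides), function(lv) {
    d <- dim(raw$cls[[lv]])
    H <- d[3L]; W <- d[4L]
    l <- seq_len(H * W)
    hh <- ((l - 1L) %% H) + 1L
    ww <- ((l - 1L) %/% H) + 1L
    list(H = H, W = W,
         cx = (ww - 0.5) * strides[lv], cy = (hh - 0.5) * strides[lv])
  })
  dcls <- lapply(raw$cls, zeros_like)
  dreg <- lapply(raw$reg, zeros_like)
  tcls <- lapply(raw$cls, zeros_like)
  npos <- 0
  pos <- vector("list", N)
  for (n in seq_len(N)) {
    tg <- targets[[n]]
    if (is.null(tg) || nrow(tg) == 0L) { pos[[n]] <- NULL; next }
    plist <- NULL
    for (gi in seq_len(nrow(tg))) {
      a <- assign_anchors(tg[gi, 2:5], grids)
      plist <- rbind(plist, cbind(a, gi))
    }
    # an anchor keeps only its first (closest) ground truth
    dup <- duplicated(plist[, 1:2, drop = FALSE])
    plist <- plist[!dup, , drop = FALSE]
    pos[[n]] <- plist
    npos <- npos + nrow(plist)
    for (r in seq_len(nrow(plist))) {
      lv <- plist[r, 1L]; l <- plist[r, 2L]; gi <- plist[r, 3L]
      H <- grids[[lv]]$H
      hh <- ((l - 1L) %% H) + 1L; ww <- ((l - 1L) %/% H) + 1L
      tcls[[lv]][n, tg[gi, 1L] + 1L, hh, ww] <- 1
    }
  }
  npos <- max(1, npos)
  # BCE classification over all anchors
  cls_loss <- 0
  for (lv in 1:3) {
    z <- raw$cls[[lv]]; t <- tcls[[lv]]
    cls_loss <- cls_loss + sum(pmax(z, 0) - z * t + log1p(exp(-abs(z))))
    dcls[[lv]] <- gains$cls * (1 / (1 + exp(-z)) - t) / npos
  }
  cls_loss <- gains$cls * cls_loss / npos
  # box + DFL on positives
  box_loss <- 0; dfl_loss <- 0
  bins <- 0:(R - 1L)
  for (n in seq_len(N)) {
    plist <- pos[[n]]
    if (is.null(plist) || nrow(plist) == 0L) next
    tg <- targets[[n]]
    for (r in seq_len(nrow(plist))) {
      lv <- plist[r, 1L]; l <- plist[r, 2L]; gi <- plist[r, 3L]
      s <- strides[lv]
      g <- grids[[lv]]
      H <- g$H
      hh <- ((l - 1L) %% H) + 1L; ww <- ((l - 1L) %/% H) + 1L
      ax <- g$cx[l]; ay <- g$cy[l]
      gt <- tg[gi, 2:5]
      z <- matrix(raw$reg[[lv]][n, , hh, ww], R, 4L)      # bins x sides
      zs <- sweep(z, 2L, apply(z, 2L, max))
      p <- sweep(exp(zs), 2L, colSums(exp(zs)), "/")
      dist <- colSums(p * bins)                            # stride units
      # CIoU on the decoded box
      mkbox <- function(d) c(ax - d[1] * s, ay - d[2] * s,
                             ax + d[3] * s, ay + d[4] * s)
      lci <- 1 - ciou(mkbox(dist), gt)
      box_loss <- box_loss + lci
      eps <- 1e-4
      ddist <- numeric(4L)
      for (si in 1:4) {
        d1 <- dist; d1[si] <- d1[si] + eps
        d2 <- dist; d2[si] <- d2[si] - eps
        ddist[si] <- ((1 - ciou(mkbox(d1), gt)) - (1 - ciou(mkbox(d2), gt))) /
          (2 * eps)
      }
      # DFL: interpolated cross-entropy on the two adjacent bins
      tdist <- pmin(pmax(c(ax - gt[1], ay - gt[2], gt[3] - ax, gt[4] - ay) / s,
                         0), R - 1 - 1e-3)
      tl <- floor(tdist); wr <- tdist - tl; wl <- 1 - wr
      dz <- matrix(0, R, 4L)
      for (si in 1:4) {
        pl <- p[tl[si] + 1L, si]; pr <- p[min(tl[si] + 2L, R), si]
        dfl_loss <- dfl_loss - (wl[si] * log(pl + 1e-12) +
                                wr[si] * log(pr + 1e-12))
        tvec <- numeric(R)
        tvec[tl[si] + 1L] <- wl[si]
        tvec[min(tl[si] + 2L, R)] <- tvec[min(tl[si] + 2L, R)] + wr[si]
        # d(dfl)/dz = p - t ; d(box)/dz via softmax expectation jacobian
        dz[, si] <- gains$dfl * (p[, si] - tvec) / (4 * npos) +
          gains$box * ddist[si] * p[, si] * (bins - dist[si]) / npos
      }
      dreg[[lv]][n, , hh, ww] <- dreg[[lv]][n, , hh, ww] + as.vector(dz)
    }
  }
  box_loss <- gains$box * box_loss / npos
  dfl_loss <- gains$dfl * dfl_loss / (4 * npos)
  list(total = box_loss + cls_loss + dfl_loss,
       box = box_loss, cls = cls_loss, dfl = dfl_loss,
       dhead = list(reg = dreg, cls = dcls))
}
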