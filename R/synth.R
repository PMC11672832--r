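# Synthetic overhead-image dataset ----------------------------------------
#
# Emulates the study's data regime: overhead alleyway images (native render
# 1297 x 720) containing one labeled tail-region object per image, five
# ordinal classes. Classes differ through a single monotone latent (ellipse
# elongation plus the depth of a ring-shaped contour groove), so adjacent
# classes are the hardest to separate -- mirroring the ordinal structure of
# body-condition scores. Variable brightness and background clutter are
# always on; motion blur is a separate evaluation-time perturbation.

#' Synthetic dataset configuration
#'
#' @param n_per_class images per class (length 5).
#' @param image_size `c(width, height)` of the rendered images; default
#'   `c(1297, 720)`, the native camera resolution being emulated.
#' @param seed RNG seed; the full dataset is reproducible from it.
#' @param class_aspect per-class ellipse elongation (strictly monotone).
#' @param class_ring per-class contour-groove depth (strictly monotone).
#' @param brightness_range multiplicative global brightness jitter.
#' @param clutter_level expected number of background clutter blobs per
#'   image divided by 5 (0 disables clutter).
#' @param class_names class label strings for the dataset YAML.
#' @return a `bcsy_synth_config`.
#' @export
synth_config <- function(n_per_class = rep(40L, 5L),
                         image_size = c(1297L, 720L), seed = 0L,
                         class_aspect = seq(1.15, 2.05, length.out = 5L),
                         class_ring = seq(0.15, 0.75, length.out = 5L),
                         brightness_range = c(0.75, 1.25),
                         clutter_level = 0.3,
                         class_names = c("3.25", "3.5", "3.75", "4.0",
                                         "4.25")) {
  if (length(n_per_class) != 5L || any(n_per_class < 0))
    stop("n_per_class must be 5 non-negative counts")
  if (any(diff(class_aspect) <= 0) || any(diff(class_ring) <= 0))
    stop("class shape parameters must be strictly monotone across classes")
  structure(list(n_per_class = as.integer(n_per_class),
                 image_size = as.integer(image_size), seed = as.integer(seed),
                 class_aspect = class_aspect, class_ring = class_ring,
                 brightness_range = brightness_range,
                 clutter_level = clutter_level, class_names = class_names),
            class = "bcsy_synth_config")
}

# render one image; returns list(img = (3,H,W), box = c(cx,cy,w,h) normalized,
# latent = c(aspect, ring))
render_synth_image <- function(cfg, class_id) {
  W <- cfg$image_size[1L]; H <- cfg$image_size[2L]
  X <- matrix(seq_len(W), H, W, byrow = TRUE)
  Y <- matrix(seq_len(H), H, W)
  # background: low-frequency shading + grain
  f1 <- stats::runif(1, 0.5, 2); f2 <- stats::runif(1, 0.5, 2)
  p1 <- stats::runif(2)
  bg <- 0.30 + 0.05 * sin(2 * pi * (f1 * X / W + p1[1L])) *
    cos(2 * pi * (f2 * Y / H + p1[2L])) +
    matrix(stats::rnorm(H * W, 0, 0.02), H, W)
  # clutter blobs
  nblob <- stats::rpois(1, cfg$clutter_level * 5)
  for (i in seq_len(nblob)) {
    bx <- stats::runif(1, 1, W); by <- stats::runif(1, 1, H)
    br <- stats::runif(1, 0.02, 0.06) * W
    amp <- stats::runif(1, -0.10, 0.10)
    bg <- bg + amp * exp(-((X - bx)^2 + (Y - by)^2) / (2 * br^2))
  }
  # tail-region object
  aspect <- cfg$class_aspect[class_id + 1L] + stats::rnorm(1, 0, 0.04)
  ring <- cfg$class_ring[class_id + 1L] + stats::rnorm(1, 0, 0.04)
  rx <- stats::runif(1, 0.055, 0.085) * W
  ry <- rx / aspect
  cx <- stats::runif(1, 0.18, 0.82) * W
  cy <- stats::runif(1, 0.22, 0.78) * H
  r2 <- ((X - cx) / rx)^2 + ((Y - cy) / ry)^2
  r <- sqrt(r2)
  body <- 0.78 - 0.06 * r2
  groove <- ring * 0.38 * exp(-((r - 0.62) / 0.13)^2)
  obj <- body - groove
  alpha <- pmin(1, pmax(0, (1.08 - r) / 0.16))
  img1 <- bg * (1 - alpha) + obj * alpha
  img1 <- img1 * stats::runif(1, cfg$brightness_range[1L],
                              cfg$brightness_range[2L])
  img1 <- pmin(pmax(img1, 0), 1)
  img <- array(0, c(3L, H, W))
  tint <- c(1, 0.97, 0.92)
  for (c in 1:3) img[c, , ] <- img1 * tint[c]
  list(img = img,
       box = c(cx / W, cy / H, 2 * rx / W, 2 * ry / H),
       latent = c(aspect = aspect, ring = ring))
}

#' Generate a synthetic YOLO-format dataset
#'
#' Renders `n_per_class` images per class, writes PNG images, one-row YOLO
#' label files (`class cx cy w h`, normalized), a per-class 8:2 train/val
#' split, file lists, a dataset YAML and a JSON manifest. Byte-reproducible
#' from `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @param out_dir output directory (created).
#' @param split_ratio train fraction of the per-class split.
#' @return a `bcsy_manifest`: `data` (one row per image: file, class,
#'   split, box, latents), `dir`, `classes`.
#' @export
generate_dataset <- function(cfg, out_dir, split_ratio = 0.8) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "labels"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  set.seed(cfg$seed)
  rows <- list()
  n <- 0L
  for (k in 0:4) {
    for (i in seq_len(cfg$n_per_class[k + 1L])) {
      r <- render_synth_image(cfg, k)
      stem <- sprintf("img_c%d_%04d", k, i)
      png::writePNG(aperm(r$img, c(2L, 3L, 1L)),
                    file.path(out_dir, "images", paste0(stem, ".png")))
      writeLines(sprintf("%d %.6f %.6f %.6f %.6f", k, r$box[1L], r$box[2L],
                         r$box[3L], r$box[4L]),
                 file.path(out_dir, "labels", paste0(stem, ".txt")))
      n <- n + 1L
      rows[[n]] <- data.frame(file = paste0(stem, ".png"), class = k,
                              cx = r$box[1L], cy = r$box[2L],
                              w = r$box[3L], h = r$box[4L],
                              aspect = r$latent[1L], ring = r$latent[2L])
    }
  }
  man <- structure(list(data = do.call(rbind, rows), dir = out_dir,
                        classes = cfg$class_names),
                   class = "bcsy_manifest")
  man <- split_per_class(man, split_ratio, cfg$seed)
  write_manifest(man, cfg)
  man
}

#' Manifest from bare per-class counts
#'
#' Builds a placeholder manifest (no files on disk) so the per-class
#' splitter can be applied to stated dataset sizes.
#'
#' @param n_per_class integer counts per class.
#' @return a `bcsy_manifest` with synthetic row entries.
#' @export
manifest_from_counts <- function(n_per_class) {
  rows <- do.call(rbind, lapply(seq_along(n_per_class), function(k) {
    n <- n_per_class[k]
    if (n == 0L) return(NULL)
    data.frame(file = sprintf("c%d_%d.png", k - 1L, seq_len(n)),
               class = k - 1L)
  }))
  structure(list(data = rows, dir = NULL, classes = as.character(
    seq_along(n_per_class) - 1L)), class = "bcsy_manifest")
}

#' Per-class train/validation split
#'
#' Within every class, `floor(ratio * n)` images go to the training split
#' and the remainder to validation (rounding rule: floor for train), after
#' a seeded shuffle.
#'
#' @param manifest a `bcsy_manifest`.
#' @param ratio train fraction, strictly between 0 and 1.
#' @param seed shuffle seed.
#' @return the manifest with a `split` column added to `$data`.
#' @export
split_per_class <- function(manifest, ratio = 0.8, seed = 0L) {
  if (!(ratio > 0 && ratio < 1)) stop("ratio must be strictly inside (0, 1)")
  d <- manifest$data
  d$split <- "val"
  set.seed(seed)
  for (k in unique(d$class)) {
    idx <- which(d$class == k)
    idx <- idx[sample(length(idx))]
    ntr <- floor(ratio * length(idx))
    d$split[idx[seq_len(ntr)]] <- "train"
  }
  manifest$data <- d
  manifest
}

write_manifest <- function(man, cfg) {
  d <- man$data
  jsonlite::write_json(list(classes = man$classes,
                            image_size = cfg$image_size,
                            seed = cfg$seed,
                            images = d),
                       file.path(man$dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (sp in c("train", "val"))
    writeLines(file.path("images", d$file[d$split == sp]),
               file.path(man$dir, paste0(sp, ".txt")))
  nm <- as.list(man$classes)
  names(nm) <- as.character(seq_along(man$classes) - 1L)
  yaml::write_yaml(list(path = normalizePath(man$dir), train = "train.txt",
                        val = "val.txt", names = nm),
                   file.path(man$dir, "dataset.yaml"))
  invisible(man)
}

#' Read a generated dataset manifest
#'
#' @param dir dataset directory containing `manifest.json`.
#' @return a `bcsy_manifest`.
#' @export
read_manifest <- function(dir) {
  j <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  structure(list(data = j$images, dir = dir, classes = j$classes),
            class = "bcsy_manifest")
}

#' Load dataset samples into memory
#'
#' Reads the images of one split, letterboxes them to the network input
#' size, and maps the labels accordingly.
#'
#' @param manifest a `bcsy_manifest` with a split assignment.
#' @param split `"train"` or `"val"`.
#' @param input_size square network input size.
#' @return list of samples: `img` (`c(3,S,S)`), `boxes_norm`
#'   (`cbind(class, cx, cy, w, h)` normalized to the canvas), `boxes_px`
#'   (`cbind(class, x1, y1, x2, y2)` in canvas pixels).
#' @export
load_dataset_samples <- function(manifest, split = "train",
                                 input_size = 640L) {
  d <- manifest$data[manifest$data$split == split, , drop = FALSE]
  if (nrow(d) == 0L) stop("no images in split '", split, "'")
  S <- as.integer(input_size)
  lapply(seq_len(nrow(d)), function(i) {
    a <- png::readPNG(file.path(manifest$dir, "images", d$file[i]))
    if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
    img <- aperm(a[, , 1:3, drop = FALSE], c(3L, 1L, 2L))
    lb <- letterbox_image(img, S)
    bx <- cbind(d$class[i], d$cx[i], d$cy[i], d$w[i], d$h[i])
    pix <- letterbox_boxes(bx, lb, S)     # class, cx, cy, w, h in pixels
    boxes_norm <- cbind(pix[, 1L], pix[, 2L] / S, pix[, 3L] / S,
                        pix[, 4L] / S, pix[, 5L] / S)
    list(img = lb$img, boxes_norm = boxes_norm,
         boxes_px = cbind(pix[, 1L],
                          pix[, 2L] - pix[, 4L] / 2, pix[, 3L] - pix[, 5L] / 2,
                          pix[, 2L] + pix[, 4L] / 2, pix[, 3L] + pix[, 5L] / 2))
  })
}

#' Directional motion blur
#'
#' Convolves the image with a normalized line kernel of the given length
#' oriented along `direction_degrees` (0 = horizontal, the direction of
#' cattle movement along the alleyway). Edges use replicate padding, so
#' constant images are preserved exactly.
#'
#' @param img `c(C, H, W)` array.
#' @param kernel_size odd line length >= 3.
#' @param direction_degrees blur direction.
#' @return blurred image, same shape and range.
#' @export
motion_blur <- function(img, kernel_size = 35L, direction_degrees = 0) {
  k <- as.integer(kernel_size)
  if (k %% 2L == 0L || k < 3L) stop("kernel_size must be odd and >= 3")
  kern <- motion_blur_kernel(k, direction_degrees)
  d <- dim(img)
  C <- d[1L]; H <- d[2L]; W <- d[3L]
  p <- (k - 1L) %/% 2L
  yi <- c(rep(1L, p), seq_len(H), rep(H, p))
  xi <- c(rep(1L, p), seq_len(W), rep(W, p))
  padded <- img[, yi, xi, drop = FALSE]
  dim(padded) <- c(1L, dim(padded))
  w <- array(0, c(C, 1L, k, k))
  for (c in seq_len(C)) w[c, 1L, , ] <- kern
  y <- conv_fw(padded, w, NULL, stride = 1L, pad = 0L, groups = C)$y
  dim(y) <- dim(y)[-1L]
  y
}

#' Line kernel used by [motion_blur()]
#'
#' @param k odd kernel size.
#' @param direction_degrees orientation.
#' @return k x k matrix summing to 1.
#' @export
motion_blur_kernel <- function(k, direction_degrees = 0) {
  kern <- matrix(0, k, k)
  c0 <- (k + 1) / 2
  th <- direction_degrees * pi / 180
  for (t in seq(-(k - 1) / 2, (k - 1) / 2, by = 0.25)) {
    x <- round(c0 + t * cos(th))
    y <- round(c0 + t * sin(th))
    if (x >= 1 && x <= k && y >= 1 && y <= k) kern[y, x] <- 1
  }
  kern / sum(kern)
}

#' Motion-blur robustness evaluation
#'
#' Deterministically samples a fraction of the validation images, applies
#' directional motion blur to the sampled ones (in memory; the dataset on
#' disk is never modified), and evaluates the model on the clean and the
#' perturbed sets.
#'
#' @param model a `bcsy_model`.
#' @param val_samples validation samples as from [load_dataset_samples()].
#' @param fraction fraction of images to blur, in (0, 1]; 0 is allowed as a
#'   degenerate case (no perturbation).
#' @param kernel_size blur kernel length (the robustness experiment uses 35).
#' @param seed sampling seed.
#' @param direction_degrees blur direction (default horizontal).
#' @return list with `clean` and `blurred` metric reports, the blurred
#'   image indices, and `delta` (clean minus blurred mAP values).
#' @export
blur_robustness_eval <- function(model, val_samples, fraction = 0.2,
                                 kernel_size = 35L, seed = 0L,
                                 direction_degrees = 0) {
  if (length(val_samples) == 0L) stop("empty validation set")
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  set.seed(seed)
  nsel <- round(fraction * length(val_samples))
  sel <- if (nsel > 0) sort(sample(length(val_samples), nsel)) else integer()
  clean <- evaluate_model(model, val_samples)
  pert <- val_samples
  for (i in sel) pert[[i]]$img <- motion_blur(pert[[i]]$img, kernel_size,
                                              direction_degrees)
  blurred <- evaluate_model(model, pert)
  list(clean = clean, blurred = blurred, blurred_indices = sel,
       delta = c(mAP50 = clean$mAP50 - blurred$mAP50,
                 mAP50_95 = clean$mAP50_95 - blurred$mAP50_95))
}
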