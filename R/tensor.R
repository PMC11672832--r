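# Feature-map conventions ------------------------------------------------
#
# A feature map is a numeric array of dim c(C, H, W), or c(N, C, H, W) with a
# leading batch dimension. Internally everything runs batched; the helpers
# here normalize between the two forms.

#' Coerce a feature map to batched N x C x H x W form
#'
#' @param x numeric array of dim `c(C, H, W)` or `c(N, C, H, W)`.
#' @return list with `x` (4-d array) and `batched` (logical: whether the
#'   input already had a batch dimension).
#' @keywords internal
as_nchw <- function(x) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("feature map must be a rank-3 (C,H,W) or rank-4 (N,C,H,W) array")
  if (!all(is.finite(x))) stop("feature map contains non-finite entries")
  if (length(d) == 3L) {
    dim(x) <- c(1L, d)
    list(x = x, batched = FALSE)
  } else {
    list(x = x, batched = TRUE)
  }
}

#' @keywords internal
un_nchw <- function(y, batched) {
  if (!batched) {
    d <- dim(y)
    dim(y) <- d[-1]
  }
  y
}

# channel dimension of a batched map
nchan <- function(x) dim(x)[2L]

# zero array like
zeros_like <- function(x) array(0, dim(x))
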