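pad_image <- function(image, pad_x, pad_y, mode) {
  if (pad_x == 0 && pad_y == 0) return(image)
  H <- nrow(image); W <- ncol(image)
  out <- matrix(0, H + pad_x, W + pad_y)
  out[seq_len(H), seq_len(W)] <- image
  if (mode == "reflect") {
    if (pad_x > 0) {
      if (pad_x > H - 1) stop_aaawall("reflect padding wider than image")
      out[H + seq_len(pad_x), seq_len(W)] <- image[H - seq_len(pad_x), , drop = FALSE]
    }
    if (pad_y > 0) {
      if (pad_y > W - 1) stop_aaawall("reflect padding wider than image")
      out[, W + seq_len(pad_y)] <- out[, W - seq_len(pad_y), drop = FALSE]
    }
  }
  out
}

patch_starts <- function(extent, size, stride) {
  n_pos <- if (extent <= size) 1L else as.integer(ceiling((extent - size) / stride)) + 1L
  seq(0L, by = stride, length.out = n_pos)
}

#' Split an image into square patches
#'
#' Patch origins advance by `spec$stride` along each axis; the image is
#' padded (reflect or zero) so the final patches fit. The returned
#' placement index records where each patch sits so predictions can be
#' reassembled with [reassemble()].
#'
#' @param image Numeric matrix.
#' @param spec A [patch_spec()].
#' @return List with `patches` (list of `size x size` matrices) and
#'   `placement` (data.frame of 0-based `x0`, `y0` offsets plus the padded
#'   and original dimensions as attributes).
#' @export
extract_patches <- function(image, spec = patch_spec()) {
  if (!is.matrix(image) || length(image) == 0) stop_aaawall("empty image")
  H <- nrow(image); W <- ncol(image)
  sx <- patch_starts(H, spec$size, spec$stride)
  sy <- patch_starts(W, spec$size, spec$stride)
  need_x <- max(sx) + spec$size; need_y <- max(sy) + spec$size
  padded <- pad_image(image, need_x - H, need_y - W, spec$padding)
  placement <- expand.grid(x0 = sx, y0 = sy)
  patches <- lapply(seq_len(nrow(placement)), function(i) {
    x0 <- placement$x0[i]; y0 <- placement$y0[i]
    padded[x0 + seq_len(spec$size), y0 + seq_len(spec$size), drop = FALSE]
  })
  attr(placement, "orig_dim") <- c(H, W)
  attr(placement, "padded_dim") <- dim(padded)
  attr(placement, "size") <- spec$size
  list(patches = patches, placement = placement)
}

#' Reassemble per-patch predictions into a full-size map
#'
#' Overlapping patch predictions are combined by the chosen aggregation
#' (`"mean"` averages probabilities, `"max"` keeps the largest) and the
#' padded margin is cropped away, so the output has the shape of the
#' original image.
#'
#' @param patches List of matrices, one prediction per patch.
#' @param placement Placement index from [extract_patches()].
#' @param aggregate `"mean"` or `"max"`.
#' @return Matrix with the original image dimensions.
#' @export
reassemble <- function(patches, placement, aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  size <- attr(placement, "size")
  pd <- attr(placement, "padded_dim"); od <- attr(placement, "orig_dim")
  if (length(patches) != nrow(placement))
    stop_aaawall("placement rows (%d) do not match patch count (%d)",
                 nrow(placement), length(patches))
  acc <- matrix(if (aggregate == "max") -Inf else 0, pd[1], pd[2])
  cnt <- matrix(0L, pd[1], pd[2])
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    if (!all(dim(p) == c(size, size)))
      stop_aaawall("patch %d has dimensions inconsistent with placement", i)
    ix <- placement$x0[i] + seq_len(size); iy <- placement$y0[i] + seq_len(size)
    if (aggregate == "mean") {
      acc[ix, iy] <- acc[ix, iy] + p
      cnt[ix, iy] <- cnt[ix, iy] + 1L
    } else {
      acc[ix, iy] <- pmax(acc[ix, iy], p)
    }
  }
  if (aggregate == "mean") {
    if (any(cnt == 0)) stop_aaawall("placement does not cover the image")
    acc <- acc / cnt
  }
  acc[seq_len(od[1]), seq_len(od[2]), drop = FALSE]
}
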