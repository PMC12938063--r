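# bilinear / nearest sampling of a matrix at (continuous) coordinates,
# used by the geometric augmentations; out-of-range samples take `fill`
sample_image <- function(img, xs, ys, method = c("bilinear", "nearest"), fill = 0) {
  method <- match.arg(method)
  H <- nrow(img); W <- ncol(img)
  if (method == "nearest") {
    xi <- round(xs); yi <- round(ys)
    ok <- xi >= 1 & xi <= H & yi >= 1 & yi <= W
    out <- rep(fill, length(xs))
    out[ok] <- img[cbind(xi[ok], yi[ok])]
    return(out)
  }
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  out <- rep(fill, length(xs))
  ok <- x0 >= 1 & x0 + 1 <= H & y0 >= 1 & y0 + 1 <= W
  if (any(ok)) {
    i00 <- img[cbind(x0[ok], y0[ok])]; i10 <- img[cbind(x0[ok] + 1, y0[ok])]
    i01 <- img[cbind(x0[ok], y0[ok] + 1)]; i11 <- img[cbind(x0[ok] + 1, y0[ok] + 1)]
    out[ok] <- i00 * (1 - fx[ok]) * (1 - fy[ok]) + i10 * fx[ok] * (1 - fy[ok]) +
      i01 * (1 - fx[ok]) * fy[ok] + i11 * fx[ok] * fy[ok]
  }
  out
}

# rotate by `angle` (degrees) about the image centre and scale by `zoom`,
# bilinear for images, nearest-neighbour for masks so they stay binary
warp_image <- function(img, angle, zoom, method) {
  H <- nrow(img); W <- ncol(img)
  cx <- (H + 1) / 2; cy <- (W + 1) / 2
  th <- angle * pi / 180
  g <- expand.grid(x = seq_len(H), y = seq_len(W))
  # inverse map: output pixel -> source location
  dx <- (g$x - cx) / zoom; dy <- (g$y - cy) / zoom
  xs <- cx + cos(th) * dx - sin(th) * dy
  ys <- cy + sin(th) * dx + cos(th) * dy
  matrix(sample_image(img, xs, ys, method), H, W)
}

#' Randomly augment an image/mask pair
#'
#' Applies, under a fixed seed, random horizontal/vertical flips, a random
#' rotation, and a random zoom identically to image and mask (nearest
#' neighbour for the mask so it stays binary), plus a random intensity
#' scale applied to the image only.
#'
#' @param image Numeric matrix.
#' @param mask Binary matrix of the same shape.
#' @param seed Integer seed; the same seed reproduces the same transform.
#' @param rotation_range Max absolute rotation (degrees); default 15.
#' @param zoom_range Length-2 zoom factor range; default `c(0.9, 1.1)`.
#' @param intensity_range Length-2 intensity scale range; default `c(0.9, 1.1)`.
#' @return List with `image` and `mask`.
#' @export
augment_pair <- function(image, mask, seed,
                         rotation_range = 15, zoom_range = c(0.9, 1.1),
                         intensity_range = c(0.9, 1.1)) {
  assert_binary_mask(mask)
  if (!all(dim(image) == dim(mask))) stop_aaawall("image/mask shape mismatch")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  flip_h <- runif(1) < 0.5; flip_v <- runif(1) < 0.5
  angle <- runif(1, -rotation_range, rotation_range)
  zoom <- runif(1, zoom_range[1], zoom_range[2])
  gain <- runif(1, intensity_range[1], intensity_range[2])
  if (flip_h) { image <- image[nrow(image):1, , drop = FALSE]; mask <- mask[nrow(mask):1, , drop = FALSE] }
  if (flip_v) { image <- image[, ncol(image):1, drop = FALSE]; mask <- mask[, ncol(mask):1, drop = FALSE] }
  if (abs(angle) > 1e-12 || abs(zoom - 1) > 1e-12) {
    image <- warp_image(image, angle, zoom, "bilinear")
    mask <- warp_image(mask, angle, zoom, "nearest")
  }
  list(image = image * gain, mask = mask)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
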