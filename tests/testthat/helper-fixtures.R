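# Programmatic fixtures shared across the suite.

disk_mask <- function(r_px, grid = ceiling(2 * r_px) + 8, center = NULL) {
  if (is.null(center)) center <- c((grid + 1) / 2, (grid + 1) / 2)
  xs <- matrix(seq_len(grid), grid, grid) - center[1]
  ys <- matrix(seq_len(grid), grid, grid, byrow = TRUE) - center[2]
  matrix(as.integer(xs^2 + ys^2 <= r_px^2), grid, grid)
}

circle_contour <- function(r, center = c(0, 0), n = 256, pixel_size = 1) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  slice_contour(cbind(center[1] + r * cos(th), center[2] + r * sin(th)),
                pixel_size = pixel_size)
}

rotation_matrix <- function(theta, axis) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
}

polygon_area_of <- function(ct) {
  p <- ct$points
  abs(sum(p[, 1] * c(p[-1, 2], p[1, 2]) - c(p[-1, 1], p[1, 1]) * p[, 2]) / 2)
}

# small noiseless tube phantom reused by several files
tube_spec <- function(...) {
  fusiform_spec(r0 = 1.5, rmax = 1.5, n_slices = 15, grid = 64,
                pixel_size = 0.8, slice_spacing = 4, noise_sd = 0, ...)
}
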