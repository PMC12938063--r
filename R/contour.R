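#' Slice contour
#'
#' An ordered closed polygon in pixel coordinates `(x, y)` (1-based, `x`
#' along the first matrix dimension), with the in-plane pixel size
#' attached for physical measurements.
#'
#' @param points Numeric matrix `n x 2`.
#' @param pixel_size In-plane pixel size in mm/pixel.
#' @param closed Logical (default TRUE).
#' @return A `slice_contour` object.
#' @export
slice_contour <- function(points, pixel_size = 1, closed = TRUE) {
  points <- as.matrix(points)
  if (ncol(points) != 2 || nrow(points) < 3)
    stop_aaawall("a contour needs at least 3 points in 2 columns")
  colnames(points) <- c("x", "y")
  structure(list(points = points, pixel_size = pixel_size, closed = closed),
            class = "slice_contour")
}

#' Extract the ordered boundary contour of a mask
#'
#' Labels the foreground, keeps the largest connected component, and
#' traces its ordered closed boundary. The traced path runs through the
#' centres of the outermost foreground pixels, which sits about half a
#' pixel inside the true region boundary; by default each point is
#' therefore pushed outward along the local normal by the offset that
#' makes the polygon area match the pixel-count area (a nearly unbiased
#' area estimator), so that areas, perimeters and round-trip
#' rasterisation are unbiased.
#'
#' @param mask Binary matrix.
#' @param pixel_size mm/pixel, attached to the contour.
#' @param min_pixels Components smaller than this are rejected (default 5)
#'   so degenerate single-pixel masks raise an error.
#' @param half_pixel_offset Apply the half-pixel boundary correction
#'   (default TRUE).
#' @return A `slice_contour`.
#' @export
mask_to_contour <- function(mask, pixel_size = 1, min_pixels = 5L,
                            half_pixel_offset = TRUE) {
  assert_binary_mask(mask)
  if (sum(mask) == 0) stop_aaawall("empty mask: no foreground pixels")
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  if (sizes[keep] < min_pixels)
    stop_aaawall("largest component has %d pixels (< %d): degenerate mask",
                 sizes[keep], min_pixels)
  comp <- matrix(as.integer(lab == keep), nrow(mask), ncol(mask))
  oc <- EBImage::ocontour(comp)[[1]]   # 0-based (dim1, dim2) indices
  pts <- cbind(x = oc[, 1] + 1, y = oc[, 2] + 1)
  if (half_pixel_offset && nrow(pts) >= 3) {
    n <- nrow(pts)
    nxt <- pts[c(2:n, 1), , drop = FALSE]
    prv <- pts[c(n, 1:(n - 1)), , drop = FALSE]
    tang <- nxt - prv
    tl <- pmax(sqrt(rowSums(tang^2)), 1e-12)
    # outward = rotated tangent, oriented away from the component centroid
    nrm <- cbind(tang[, 2], -tang[, 1]) / tl
    ctr <- colMeans(pts)
    flip <- rowSums(nrm * sweep(pts, 2, ctr)) < 0
    nrm[flip, ] <- -nrm[flip, ]
    # offset calibrated so the polygon area equals the pixel-count area
    a_gap <- sizes[keep] - polygon_area(pts)
    delta <- min(max(a_gap / max(polygon_perimeter(pts), 1e-12), 0), 1)
    pts <- pts + delta * nrm
  }
  slice_contour(pts, pixel_size = pixel_size)
}

# cumulative arc length of a closed polygon (first point repeated at the end)
closed_polyline <- function(pts) rbind(pts, pts[1, , drop = FALSE])

#' Resample a closed contour at equal arc-length spacing
#'
#' @param contour A `slice_contour`.
#' @param n Number of output points.
#' @return Matrix `n x 2` of equally spaced points (the closing point is
#'   not duplicated).
#' @export
resample_contour <- function(contour, n) {
  pts <- closed_polyline(contour$points)
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) stop_aaawall("degenerate contour with zero perimeter")
  targets <- (seq_len(n) - 1) / n * total
  out <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    j <- findInterval(targets[i], cum, rightmost.closed = TRUE)
    j <- min(j, nrow(pts) - 1)
    f <- if (seg[j] > 0) (targets[i] - cum[j]) / seg[j] else 0
    out[i, ] <- pts[j, ] * (1 - f) + pts[j + 1, ] * f
  }
  out
}

#' Fit a closed NURBS curve to a contour
#'
#' The boundary is resampled to `n_points` arc-length-equally-spaced
#' points. In `"approximate"` mode (default) these become the control
#' points of a periodic curve with unit weights; in `"interpolate"` mode
#' the control points are solved so the curve passes through the sampled
#' points at uniform parameters; in `"lsq"` mode the control points
#' minimise the squared distance to a dense arc-length sampling of the
#' boundary (periodic least-squares approximation), which averages out
#' rasterisation noise without the slight inward bias of the control
#' polygon and is the preferred mode when physical measurements are
#' taken from the fitted curve.
#'
#' @param contour A `slice_contour`.
#' @param n_points Number of control points (default 24).
#' @param degree Curve degree (default 3).
#' @param mode `"approximate"`, `"interpolate"` or `"lsq"`.
#' @param dense_factor Samples per control point used by `"lsq"`
#'   (default 10).
#' @return A closed `nurbs_curve`; the contour's `pixel_size` is carried
#'   along as an attribute.
#' @export
fit_contour <- function(contour, n_points = 24L, degree = 3L,
                        mode = c("approximate", "interpolate", "lsq"),
                        dense_factor = 10L) {
  mode <- match.arg(mode)
  if (n_points < degree + 1) stop_aaawall("n_points must be at least degree + 1")
  if (nrow(contour$points) < 3) stop_aaawall("too few boundary points")
  q <- resample_contour(contour, n_points)
  curve <- nurbs_curve(q, degree = degree, closed = TRUE)
  fold_basis <- function(t) {
    N <- curve_basis(curve, t)
    folded <- N[seq_len(n_points)]
    folded[seq_len(curve$degree)] <- folded[seq_len(curve$degree)] +
      N[n_points + seq_len(curve$degree)]
    folded
  }
  if (mode == "interpolate") {
    ts <- (seq_len(n_points) - 1) / n_points
    B <- t(vapply(ts, fold_basis, numeric(n_points)))
    curve$control <- solve(B, q)
  } else if (mode == "lsq") {
    nd <- dense_factor * n_points
    qd <- resample_contour(contour, nd)
    ts <- (seq_len(nd) - 1) / nd
    B <- t(vapply(ts, fold_basis, numeric(n_points)))
    curve$control <- qr.solve(B, qd)
  }
  attr(curve, "pixel_size") <- contour$pixel_size
  curve
}

#' Rasterise a closed curve to a binary mask
#'
#' The curve is sampled densely (`samples_per_ctrl` samples per control
#' point) and the polygon interior filled with the even-odd rule on pixel
#' centres.
#'
#' @param curve A closed `nurbs_curve` in pixel coordinates.
#' @param shape Length-2 integer grid dimensions `(nx, ny)`.
#' @param samples_per_ctrl Dense sampling factor (default 10).
#' @return Binary matrix of dimension `shape`.
#' @export
curve_to_mask <- function(curve, shape, samples_per_ctrl = 10L) {
  if (!curve$closed) stop_aaawall("curve must be closed to rasterise")
  n_s <- samples_per_ctrl * nrow(curve$control)
  ts <- (seq_len(n_s) - 1) / n_s
  poly <- evaluate_curve(curve, ts)
  fill_polygon(poly, shape)
}

# even-odd scanline fill of a closed polygon over pixel centres (1..nx, 1..ny)
fill_polygon <- function(poly, shape) {
  nx <- shape[1]; ny <- shape[2]
  mask <- matrix(0L, nx, ny)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- c(poly[-1, 1], poly[1, 1]); y2 <- c(poly[-1, 2], poly[1, 2])
  for (row in seq_len(ny)) {            # scan along y = row
    yl <- pmin(y1, y2); yh <- pmax(y1, y2)
    hit <- which(yl <= row & yh > row)  # half-open rule avoids double counts
    if (length(hit) < 2) next
    xc <- x1[hit] + (row - y1[hit]) * (x2[hit] - x1[hit]) / (y2[hit] - y1[hit])
    xc <- sort(xc)
    for (k in seq(1, length(xc) - 1, by = 2)) {
      lo <- max(1, ceiling(xc[k])); hi <- min(nx, floor(xc[k + 1]))
      if (hi >= lo) mask[lo:hi, row] <- 1L
    }
  }
  mask
}

#' Refine a mask through the NURBS pipeline
#'
#' Convenience wrapper: boundary extraction, curve fit, re-rasterisation.
#' This is the programmatic equivalent of accepting a smoothed contour in
#' an interactive editing session.
#'
#' @param mask Binary matrix.
#' @param n_points,degree,mode Passed to [fit_contour()].
#' @return Binary matrix of the same shape.
#' @export
refine_mask <- function(mask, n_points = 24L, degree = 3L, mode = "approximate") {
  ct <- mask_to_contour(mask)
  cv <- fit_contour(ct, n_points = n_points, degree = degree, mode = mode)
  curve_to_mask(cv, dim(mask))
}

#' Write / read contour stacks as CSV
#'
#' Columns: `slice_index`, `point_index`, `x_px`, `y_px`. Physical
#' scaling travels in a JSON sidecar written next to the CSV.
#'
#' @param stack A `contour_stack` (see [contour_stack()]).
#' @param path CSV path.
#' @return `write_contours_csv` returns `path` invisibly;
#'   `read_contours_csv` returns a `contour_stack`.
#' @export
write_contours_csv <- function(stack, path) {
  rows <- do.call(rbind, lapply(seq_along(stack$contours), function(i) {
    p <- stack$contours[[i]]$points
    data.frame(slice_index = i, point_index = seq_len(nrow(p)),
               x_px = p[, 1], y_px = p[, 2])
  }))
  write.csv(rows, path, row.names = FALSE)
  meta <- list(pixel_size_mm = stack$pixel_size, slice_spacing_mm = stack$slice_spacing)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_contours_csv
#' @export
read_contours_csv <- function(path) {
  rows <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  contours <- lapply(split(rows, rows$slice_index), function(df) {
    slice_contour(cbind(df$x_px, df$y_px), pixel_size = meta$pixel_size_mm)
  })
  contour_stack(unname(contours), slice_spacing = meta$slice_spacing_mm,
                pixel_size = meta$pixel_size_mm)
}
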