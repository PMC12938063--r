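test_that("clamped-uniform knot vectors match the standard construction", {
  expect_equal(compute_knot_vector(4, 2, closed = FALSE),
               c(0, 0, 0, 0.5, 1, 1, 1))
  expect_equal(compute_knot_vector(4, 1, closed = FALSE),
               c(0, 0, 1 / 3, 2 / 3, 1, 1))
  for (n in 4:9) for (p in 1:3) {
    kv <- compute_knot_vector(n, p, closed = FALSE)
    expect_false(is.unsorted(kv))
    expect_length(kv, n + p + 1)
    kvc <- compute_knot_vector(n, p, closed = TRUE)
    expect_false(is.unsorted(kvc))
  }
  expect_error(compute_knot_vector(3, 3), "control points")
})

test_that("basis functions form a partition of unity", {
  set.seed(42)
  ctrl <- cbind(cos(2 * pi * (0:15) / 16), sin(2 * pi * (0:15) / 16))
  closed <- nurbs_curve(ctrl, closed = TRUE)
  open <- nurbs_curve(ctrl, closed = FALSE)
  ts <- runif(1000)
  for (cv in list(closed, open)) {
    err <- vapply(ts, function(t) abs(sum(curve_basis(cv, t)) - 1), numeric(1))
    expect_lt(max(err), 1e-9)
  }
})

test_that("curve evaluation matches hand-checkable cases", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  # equal weights cancel: rational curve with w = 5 equals w = 1
  c1 <- nurbs_curve(sq, weights = rep(1, 4), degree = 2, closed = TRUE)
  c5 <- nurbs_curve(sq, weights = rep(5, 4), degree = 2, closed = TRUE)
  ts <- seq(0, 1, length.out = 33)
  expect_equal(evaluate_curve(c1, ts), evaluate_curve(c5, ts), tolerance = 1e-12)
  # degree 1: knot-span midpoint is the control point midpoint
  cl <- nurbs_curve(sq, degree = 1, closed = FALSE)
  expect_equal(unname(evaluate_curve(cl, 1 / 6)), matrix(c(0.5, 0), 1),
               tolerance = 1e-12)
  expect_equal(unname(evaluate_curve(cl, 0)), matrix(c(0, 0), 1))
  expect_equal(unname(evaluate_curve(cl, 1)), matrix(c(0, 1), 1))
  expect_error(evaluate_curve(cl, 1.5), "\\[0, 1\\]")
})

test_that("increasing a weight pulls the curve toward its control point", {
  ctrl <- cbind(cos(2 * pi * (0:11) / 12), sin(2 * pi * (0:11) / 12)) * 10
  t_star <- 3 / 12   # parameter in the support of control point 4
  dists <- vapply(c(1, 10, 100), function(w) {
    cv <- set_control_weight(nurbs_curve(ctrl, closed = TRUE), 4, w)
    sqrt(sum((evaluate_curve(cv, t_star) - ctrl[4, ])^2))
  }, numeric(1))
  expect_true(all(diff(dists) < 0))
})

test_that("curve lies in the convex hull of its control points", {
  set.seed(3)
  ctrl <- cbind(runif(10, 0, 10), runif(10, 0, 10))
  cv <- nurbs_curve(ctrl, closed = TRUE)
  pts <- evaluate_curve(cv, seq(0, 1, length.out = 400))
  hull <- chull(ctrl)
  hp <- ctrl[hull, , drop = FALSE]
  # all sampled points inside the hull polygon (signed-area test per edge)
  nh <- nrow(hp)
  for (i in seq_len(nh)) {
    a <- hp[i, ]; b <- hp[if (i == nh) 1 else i + 1, ]
    cross <- (b[1] - a[1]) * (pts[, 2] - a[2]) - (b[2] - a[2]) * (pts[, 1] - a[1])
    expect_true(all(cross <= 1e-9) || all(cross >= -1e-9))
  }
})

test_that("contour fitting resamples at equal arc length", {
  ct <- circle_contour(10, c(20, 20), n = 500)
  q <- resample_contour(ct, 24)
  seg <- sqrt(rowSums((rbind(q[-1, ], q[1, ]) - q)^2))
  expect_lt(diff(range(seg)) / mean(seg), 0.01)
  # n_points equal to the contour point count reproduces the polygon
  ct4 <- slice_contour(rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4)))
  q4 <- resample_contour(ct4, 4)
  expect_equal(sort(apply(q4, 1, paste, collapse = ",")),
               sort(apply(ct4$points, 1, paste, collapse = ",")))
})

test_that("fitted circle deviates by less than a pixel for n >= 16, p = 3", {
  ct <- circle_contour(10, c(20, 20), n = 720)
  for (n in c(16, 24, 32)) {
    cv <- fit_contour(ct, n_points = n, degree = 3)
    pts <- evaluate_curve(cv, seq(0, 0.999, length.out = 720))
    r <- sqrt(rowSums((pts - 20)^2))
    expect_lt(max(abs(r - 10)), 1)
  }
  # interpolation mode passes through the resampled points
  cvi <- fit_contour(ct, n_points = 24, mode = "interpolate")
  q <- resample_contour(ct, 24)
  on_curve <- evaluate_curve(cvi, (0:23) / 24)
  expect_equal(unname(on_curve), unname(q), tolerance = 1e-8)
})

test_that("control point edits are local", {
  ctrl <- cbind(cos(2 * pi * (0:15) / 16), sin(2 * pi * (0:15) / 16)) * 10
  cv <- nurbs_curve(ctrl, closed = TRUE)
  ts <- seq(0, 0.999, length.out = 512)
  base <- evaluate_curve(cv, ts)
  # identity move changes nothing
  expect_identical(evaluate_curve(move_control_point(cv, 5, ctrl[5, ]), ts), base)
  # moving P_5 leaves samples outside its basis support bit-identical
  moved <- move_control_point(cv, 5, ctrl[5, ] + c(3, -2))
  after <- evaluate_curve(moved, ts)
  support <- vapply(ts, function(t) curve_basis(cv, t)[5] > 0, logical(1))
  expect_identical(after[!support, ], base[!support, ])
  expect_false(identical(after[support, ], base[support, ]))
  # convex-combination bound: |delta c| <= |delta P| everywhere
  delta <- sqrt(rowSums((after - base)^2))
  expect_lte(max(delta), sqrt(3^2 + 2^2) + 1e-12)
  expect_error(move_control_point(cv, 99, c(0, 0)), "index")
})

test_that("mask boundaries are extracted from the largest component", {
  mask <- disk_mask(10, 40)
  ct <- mask_to_contour(mask)
  # enclosed area agrees with the foreground pixel count within 5%
  expect_lt(abs(polygon_area_of(ct) - sum(mask)) / sum(mask), 0.05)
  # two disjoint disks: only the larger is traced
  two <- disk_mask(10, 64, center = c(20, 20)) +
    disk_mask(5, 64, center = c(50, 50))
  ct2 <- mask_to_contour(two)
  expect_true(all(rowSums(sweep(ct2$points, 2, c(20, 20))^2) < 15^2))
  # degenerate single-pixel component is rejected
  single <- matrix(0L, 16, 16); single[8, 8] <- 1L
  expect_error(mask_to_contour(single), "degenerate")
  expect_error(mask_to_contour(matrix(0L, 8, 8)), "empty")
})

test_that("mask -> curve -> mask round trip preserves a disk", {
  for (r in c(12, 20)) {
    mask <- disk_mask(r)
    cv <- fit_contour(mask_to_contour(mask))
    back <- curve_to_mask(cv, dim(mask))
    m <- overlap_metrics(confusion(back, mask))
    expect_gte(m$dsc, 0.98)
  }
  # curve wholly outside the grid rasterises to an empty mask
  far <- nurbs_curve(cbind(cos(2 * pi * (0:7) / 8), sin(2 * pi * (0:7) / 8)) + 100,
                     closed = TRUE)
  expect_equal(sum(curve_to_mask(far, c(16, 16))), 0)
  open_cv <- nurbs_curve(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), closed = FALSE)
  expect_error(curve_to_mask(open_cv, c(16, 16)), "closed")
})

test_that("rasterised area matches the shoelace area of the sampled polyline", {
  mask <- disk_mask(15)
  cv <- fit_contour(mask_to_contour(mask))
  ts <- (seq_len(240) - 1) / 240
  poly <- evaluate_curve(cv, ts)
  shoelace <- abs(sum(poly[, 1] * c(poly[-1, 2], poly[1, 2]) -
                        c(poly[-1, 1], poly[1, 1]) * poly[, 2]) / 2)
  filled <- sum(curve_to_mask(cv, dim(mask)))
  expect_lt(abs(filled - shoelace) / shoelace, 0.02)
})

test_that("refinement is approximately idempotent on smooth phantom masks", {
  mask <- disk_mask(20)
  m1 <- refine_mask(mask)
  m2 <- refine_mask(m1)
  d1 <- overlap_metrics(confusion(m1, mask))$dsc
  d2 <- overlap_metrics(confusion(m2, m1))$dsc
  expect_lt(abs(d1 - d2), 0.005)
  # in interpolation mode the second pass changes almost nothing
  mi1 <- refine_mask(mask, mode = "interpolate")
  mi2 <- refine_mask(mi1, mode = "interpolate")
  expect_gte(overlap_metrics(confusion(mi2, mi1))$dsc, 0.99)
})
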