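test_that("hydraulic diameter has its closed-form values", {
  # circle of diameter D: 4(pi D^2/4)/(pi D) = D
  expect_equal(hydraulic_diameter(circle_contour(15, c(0, 0), 2000,
                                                 pixel_size = 1)),
               3, tolerance = 1e-4)
  # square of side s: 4 s^2 / 4s = s
  sq <- slice_contour(rbind(c(0, 0), c(20, 0), c(20, 20), c(0, 20)),
                      pixel_size = 1)
  expect_equal(hydraulic_diameter(sq), 2)
  # ellipse a = 2, b = 1 (cm, pixel_size 10 mm): 4 A / P with P from
  # numerical quadrature of the arc length
  th <- 2 * pi * (seq_len(4000) - 1) / 4000
  el <- slice_contour(cbind(2 * cos(th), sin(th)), pixel_size = 10)
  fp <- function(t) sqrt(4 * sin(t)^2 + cos(t)^2)
  per <- integrate(fp, 0, 2 * pi, rel.tol = 1e-10)$value
  expect_equal(hydraulic_diameter(el), 4 * (2 * pi) / per, tolerance = 1e-4)
  expect_error(hydraulic_diameter(slice_contour(matrix(1, 3, 2))), "degenerate")
})

test_that("hydraulic diameter is rigid-motion invariant and scales with pixel size", {
  ct <- circle_contour(10, c(5, 5), 512)
  th <- 0.83
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  moved <- slice_contour(ct$points %*% R + 7, pixel_size = ct$pixel_size)
  expect_equal(hydraulic_diameter(moved), hydraulic_diameter(ct),
               tolerance = 1e-10)
  big <- slice_contour(ct$points, pixel_size = 2 * ct$pixel_size)
  expect_equal(hydraulic_diameter(big), 2 * hydraulic_diameter(ct))
})

test_that("mask-based hydraulic diameter is accurate on rasterised disks", {
  for (r_px in c(12.5, 18.75, 25, 31)) {
    mask <- disk_mask(r_px)
    dh <- measure_hydraulic_diameter(mask, pixel_size = 1)
    expect_lt(abs(dh * 10 / (2 * r_px) - 1), 0.005)
  }
})

test_that("maximum hydraulic diameter locates the bulge apex", {
  # uniform cylinder: constant profile, tie broken at the first slice
  tub <- make_volume(tube_spec())
  mx <- max_hydraulic_diameter(tub$contours)
  expect_equal(mx$slice, 1)
  expect_equal(mx$diameter_cm, 3, tolerance = 0.002)
  # fusiform bulge: argmax at the apex with value 2 rmax
  spec <- fusiform_spec(noise_sd = 0)
  vol <- make_volume(spec)
  mx2 <- max_hydraulic_diameter(vol$contours)
  expect_equal(mx2$slice, round(spec$z0))
  expect_equal(mx2$diameter_cm, 2 * spec$rmax, tolerance = 0.02 * 2 * spec$rmax)
  # single slice
  one <- contour_stack(vol$contours$contours[3], 2, 0.8)
  expect_equal(max_hydraulic_diameter(one)$slice, 1)
})

test_that("lofting two rings produces a 2m-triangle band with Euler characteristic 0", {
  m <- 24
  stack <- contour_stack(list(circle_contour(10, c(16, 16), 64),
                              circle_contour(12, c(16, 16), 64)),
                         slice_spacing = 2, pixel_size = 1)
  mesh <- loft_mesh(stack, points_per_ring = m)
  expect_equal(nrow(mesh$triangles), 2 * m)
  expect_equal(euler_characteristic(mesh), 0)
  expect_length(boundary_loops(mesh), 2)
  # z coordinates are integer multiples of the slice spacing (in cm)
  expect_true(all(abs(mesh$vertices[, 3] %% 0.2) < 1e-9 |
                    abs(mesh$vertices[, 3] %% 0.2 - 0.2) < 1e-9))
})

test_that("lofted meshes are manifold with two boundary loops", {
  vol <- make_volume(fusiform_spec(n_slices = 12, noise_sd = 0))
  mesh <- loft_mesh(vol$contours, 32)
  counts <- table(table(paste(
    pmin(c(mesh$triangles[, 1], mesh$triangles[, 2], mesh$triangles[, 3]),
         c(mesh$triangles[, 2], mesh$triangles[, 3], mesh$triangles[, 1])),
    pmax(c(mesh$triangles[, 1], mesh$triangles[, 2], mesh$triangles[, 3]),
         c(mesh$triangles[, 2], mesh$triangles[, 3], mesh$triangles[, 1])))))
  expect_true(all(names(counts) %in% c("1", "2")))
  expect_length(boundary_loops(mesh), 2)
  expect_equal(euler_characteristic(mesh), 0)
})

test_that("ring start alignment minimises the strip length over cyclic shifts", {
  m <- 12
  a <- circle_contour(10, c(0, 0), 360)$points
  b <- circle_contour(11, c(0.5, 0.3), 360)$points
  stack <- contour_stack(list(slice_contour(a), slice_contour(b)),
                         slice_spacing = 2, pixel_size = 1)
  mesh <- loft_mesh(stack, m)
  strip_len <- function(mesh) {
    tr <- mesh$triangles
    e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
    key <- !duplicated(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
    sum(sqrt(rowSums((mesh$vertices[e[key, 1], ] -
                        mesh$vertices[e[key, 2], ])^2)))
  }
  chosen <- strip_len(mesh)
  # brute force: rebuild with every cyclic shift of the second ring
  r1 <- mesh$vertices[1:m, 1:2]
  r2 <- mesh$vertices[m + 1:m, 1:2]
  for (s in 0:(m - 1)) {
    idx <- ((seq_len(m) - 1 + s) %% m) + 1
    sh <- surface_mesh(rbind(cbind(r1, 0), cbind(r2[idx, ], 0.2)),
                       mesh$triangles)
    expect_gte(strip_len(sh) + 1e-9, chosen)
  }
})

test_that("element geometry matches closed forms and isometries", {
  tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      matrix(c(1, 2, 3), 1))
  eg <- element_geometry(tri)
  expect_equal(eg$areas, 0.5)
  expect_equal(abs(eg$normals[1, 3]), 1)
  expect_equal(eg$centroids[1, ], c(1 / 3, 1 / 3, 0))
  # icosphere area converges to 4 pi R^2
  sph <- make_sphere_mesh(2, 4)
  eg2 <- element_geometry(sph)
  expect_lt(abs(sum(eg2$areas) - 4 * pi * 4) / (4 * pi * 4), 0.005)
  # rigid rotation leaves areas unchanged
  R <- rotation_matrix(1.1, c(1, 2, 3))
  rot <- surface_mesh(sph$vertices %*% t(R), sph$triangles)
  expect_equal(element_geometry(rot)$areas, eg2$areas, tolerance = 1e-12)
  # degenerate triangle is reported with its index
  bad <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                      matrix(c(1, 2, 3), 1))
  expect_error(element_geometry(bad), "degenerate")
})
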