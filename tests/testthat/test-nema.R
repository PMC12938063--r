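test_that("pressure conversion is the exact 133.322 Pa/mmHg linear map", {
  expect_equal(convert_pressure(0), 0)
  expect_equal(convert_pressure(93.3), 93.3 * 133.322 / 1e4)
  expect_equal(convert_pressure(93.3), 1.2439, tolerance = 1e-4)
  expect_equal(convert_pressure(750.062), 10, tolerance = 1e-5)
  expect_error(convert_pressure(-1), "non-negative")
  lc <- load_case(93.3, 1.5)
  expect_equal(lc$thickness_cm, 0.15)
  expect_error(load_case(93.3, 0), "positive")
})

test_that("element basis carries the metric identities", {
  # right isoceles triangle with unit legs: orthonormal edge basis
  tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      matrix(c(1, 2, 3), 1))
  eb <- element_basis(tri, 1)
  expect_equal(eb$metric, diag(2))
  expect_equal(eb$g_det, 1)
  expect_equal(sum(eb$normal * eb$g1), 0)
  expect_equal(sum(eb$normal * eb$g2), 0)
  # g_det = (2 area)^2 for arbitrary elements; metric rotation-invariant
  sph <- make_sphere_mesh(1.3, 2)
  R <- rotation_matrix(0.7, c(3, 1, 2))
  rot <- surface_mesh(sph$vertices %*% t(R), sph$triangles)
  for (f in c(1, 17, 53)) {
    eb1 <- element_basis(sph, f)
    expect_equal(eb1$g_det, (2 * eb1$area)^2, tolerance = 1e-12)
    eb2 <- element_basis(rot, f)
    expect_equal(eb2$metric, eb1$metric, tolerance = 1e-12)
  }
})

test_that("the equilibrium system is linear with geometry-only matrix", {
  mesh <- make_cylinder_mesh(1.5, 4, 16, 9)
  s1 <- assemble_equilibrium(mesh, load_case(93.3, 1.5))
  s2 <- assemble_equilibrium(mesh, load_case(186.6, 1.5))
  expect_equal(s1$A, s2$A)                 # A independent of the load level
  expect_equal(s2$b, 2 * s1$b)
  # zero pressure: b = 0, so zero stress solves the system exactly
  s0 <- assemble_equilibrium(mesh, load_case(0, 1.5))
  expect_equal(sum(abs(s0$b)), 0)
  expect_equal(as.numeric(s0$A %*% rep(0, ncol(s0$A))), s0$b)
  # a closed mesh without fixed vertices cannot be anchored
  sph <- make_sphere_mesh(1, 1)
  expect_error(assemble_equilibrium(sph, load_case(93.3, 1.5)), "fixed")
})

test_that("the closed-form cylinder field satisfies the discrete equilibrium", {
  mesh <- make_cylinder_mesh(1.5, 6, 32, 25)
  load <- load_case(93.3, 1.5)
  sys <- assemble_equilibrium(mesh, load)
  hoop <- load$pressure_ncm2 * 1.5 / load$thickness_cm
  # nodal components of the hoop-only tensor in each vertex frame
  V <- nrow(mesh$vertices)
  x <- numeric(3 * V)
  for (v in seq_len(V)) {
    circ <- c(-mesh$vertices[v, 2], mesh$vertices[v, 1], 0)
    circ <- circ / sqrt(sum(circ^2))
    S <- hoop * outer(circ, circ)
    e1 <- sys$frames$e1[v, ]; e2 <- sys$frames$e2[v, ]
    x[3 * v - 2] <- e1 %*% S %*% e1
    x[3 * v - 1] <- e1 %*% S %*% e2
    x[3 * v] <- e2 %*% S %*% e2
  }
  resid <- as.numeric(sys$A %*% x) - sys$b
  gross <- load$pressure_ncm2 * sum(element_geometry(mesh)$areas)
  expect_lt(sqrt(sum(resid^2)) / gross, 0.02)
})

test_that("cylinder stresses reproduce the Laplace law p R / h", {
  load <- load_case(93.3, 1.5)
  mesh <- make_cylinder_mesh(1.5, 6, 32, 25)
  field <- solve_stress(mesh, load)
  ref <- load$pressure_ncm2 * 1.5 / 0.15
  mid <- abs(field$centroids[, 3] - 3) < 1.2
  expect_lt(max(abs(field$principal_1[mid] / ref - 1)), 0.05)
  expect_lt(max(abs(field$principal_2[mid] / ref)), 0.05)
})

test_that("sphere stresses reproduce the Laplace law p R / (2h)", {
  load <- load_case(93.3, 1.5)
  sph <- make_sphere_mesh(1.5, 3)
  top <- which.max(sph$vertices[, 3])
  ring <- unique(as.vector(sph$triangles[rowSums(sph$triangles == top) > 0, ]))
  field <- solve_stress(sph, load, fixed_vertices = ring, max_residual = 1)
  ref <- load$pressure_ncm2 * 1.5 / (2 * 0.15)
  away <- sph$vertices[sph$triangles[, 1], 3] < 1.0
  expect_lt(max(abs(field$principal_1[away] / ref - 1)), 0.05)
  expect_lt(max(abs(field$principal_2[away] / ref - 1)), 0.05)
})

test_that("stress scales linearly in pressure and inversely in thickness", {
  mesh <- make_cylinder_mesh(1.5, 5, 20, 13)
  f1 <- solve_stress(mesh, load_case(93.3, 1.5))
  f2 <- solve_stress(mesh, load_case(186.6, 1.5))
  scale <- max(abs(f1$principal_1))
  expect_lt(max(abs(f2$principal_1 - 2 * f1$principal_1)) / scale, 1e-8)
  expect_lt(max(abs(f2$principal_2 - 2 * f1$principal_2)) / scale, 1e-8)
  fh <- solve_stress(mesh, load_case(93.3, 3.0))
  expect_lt(max(abs(fh$principal_1 - f1$principal_1 / 2)) / scale, 1e-8)
})

test_that("principal stress magnitudes are frame invariant", {
  mesh <- make_cylinder_mesh(1.2, 4, 20, 11)
  f1 <- solve_stress(mesh, load_case(100, 2))
  R <- rotation_matrix(0.7, c(1, 2, 3))
  rot <- surface_mesh(mesh$vertices %*% t(R), mesh$triangles,
                      mesh$proximal_ring, mesh$distal_ring)
  f2 <- solve_stress(rot, load_case(100, 2))
  scale <- max(abs(f1$principal_1))
  expect_lt(max(abs(f2$principal_1 - f1$principal_1)) / scale, 1e-8)
  expect_lt(max(abs(f2$principal_2 - f1$principal_2)) / scale, 1e-8)
})

test_that("cylinder hoop-stress error decreases monotonically under refinement", {
  load <- load_case(93.3, 1.5)
  ref <- load$pressure_ncm2 * 1.5 / 0.15
  errs <- vapply(c(16, 32, 64), function(nt) {
    mesh <- make_cylinder_mesh(1.5, 6, nt, round(nt * 25 / 32))
    field <- solve_stress(mesh, load)
    mid <- abs(field$centroids[, 3] - 3) < 1.2
    max(abs(field$principal_1[mid] / ref - 1))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("boundary reactions balance the total pressure load", {
  mesh <- make_cylinder_mesh(1.5, 6, 24, 17)
  field <- solve_stress(mesh, load_case(93.3, 1.5))
  fb <- force_balance(mesh, field)
  expect_lt(fb$relative_imbalance, 1e-6)
})

test_that("principal stresses diagonalise the physical tensor", {
  tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      matrix(c(1, 2, 3), 1))
  eb <- element_basis(tri, 1)
  # isotropic state
  expect_equal(principal_stresses(c(3, 0, 3), eb), c(3, 3))
  # uniaxial state
  expect_equal(principal_stresses(c(5, 0, 0), eb), c(5, 0))
  # random symmetric physical tensors against the dense eigensolver
  set.seed(8)
  for (i in 1:20) {
    s <- c(rnorm(1), rnorm(1, sd = 0.5), rnorm(1))
    M <- matrix(c(s[1], s[2], s[2], s[3]), 2, 2)
    expect_equal(principal_stresses(s, eb),
                 sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
                      decreasing = TRUE),
                 tolerance = 1e-10)
  }
})
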