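# Inverse membrane equilibrium on the imaged (deformed) surface.
#
# For a thin pressurised membrane whose deformed geometry is known, the
# in-plane Cauchy stress field is statically determinate: it satisfies
#   div_s(h * sigma) + p * n = 0
# on the surface, independent of material behaviour.  The solver
# discretises this in weak (Galerkin) form on the triangulated surface:
# the stress tensor is interpolated linearly from nodal values, and each
# free (non-boundary) vertex contributes one 3-D force-balance equation
#   sum_e  h * A_e * mean(S) . grad(N_a)  =  p * sum_e (A_e / 3) * n_e.
# Boundary-ring vertices ("fixed ends") carry no balance equations; their
# reactions absorb the residual load.  The system is linear in the nodal
# stress components and solved in least squares with a small Tikhonov
# term whose penalty is the Frobenius norm of the nodal tensors, making
# the solution frame invariant.
#
# Nodal unknowns are the components (s11, s12, s22) of the in-plane
# stress in a per-vertex orthonormal tangent frame; element quantities
# (centroid stress, principal stresses, contravariant components) are
# recovered afterwards.

#' Convert pressure from mmHg to N/cm^2
#'
#' Exact linear conversion at 133.322 Pa/mmHg: `p * 133.322 / 1e4`.
#'
#' @param p_mmHg Pressure in mmHg (non-negative).
#' @return Pressure in N/cm^2.
#' @examples
#' convert_pressure(93.3) # 1.2439 N/cm^2
#' @export
convert_pressure <- function(p_mmHg) {
  if (any(p_mmHg < 0)) stop_aaawall("pressure must be non-negative")
  p_mmHg * PA_PER_MMHG / 1e4
}

#' Load case for the membrane solver
#'
#' @param pressure_mmHg Intraluminal pressure in mmHg.
#' @param thickness_mm Uniform wall thickness in mm (default 1.5).
#' @return A `load_case` with the pressure also expressed in N/cm^2 and
#'   the thickness in cm.
#' @export
load_case <- function(pressure_mmHg = 93.3, thickness_mm = 1.5) {
  if (thickness_mm <= 0) stop_aaawall("wall thickness must be positive")
  structure(list(pressure_mmHg = pressure_mmHg,
                 pressure_ncm2 = convert_pressure(pressure_mmHg),
                 thickness_cm = thickness_mm / MM_PER_CM),
            class = "load_case")
}

#' Covariant basis, metric and normal of one element
#'
#' The element's linear shape-function map takes the covariant basis
#' vectors to be the two edge vectors `g1 = v2 - v1`, `g2 = v3 - v1`; the
#' metric is `g_ab = g_a . g_b` and its determinant equals `(2 * area)^2`.
#'
#' @param mesh A `surface_mesh`.
#' @param element Element (triangle) index.
#' @return List with `g1`, `g2`, `metric` (2x2), `g_det`, `normal`,
#'   `centroid`, `area`.
#' @export
element_basis <- function(mesh, element) {
  tr <- mesh$triangles[element, ]
  v <- mesh$vertices
  g1 <- v[tr[2], ] - v[tr[1], ]
  g2 <- v[tr[3], ] - v[tr[1], ]
  cr <- c(g1[2] * g2[3] - g1[3] * g2[2],
          g1[3] * g2[1] - g1[1] * g2[3],
          g1[1] * g2[2] - g1[2] * g2[1])
  nn <- sqrt(sum(cr^2))
  if (nn <= 2e-10) stop_aaawall("degenerate element %d", element)
  metric <- matrix(c(sum(g1 * g1), sum(g1 * g2), sum(g1 * g2), sum(g2 * g2)), 2, 2)
  list(g1 = g1, g2 = g2, metric = metric, g_det = det(metric),
       normal = cr / nn, centroid = colMeans(v[tr, ]), area = nn / 2)
}

# per-vertex orthonormal tangent frames from area-weighted vertex normals
vertex_frames <- function(mesh, eg) {
  V <- nrow(mesh$vertices)
  nrm <- matrix(0, V, 3)
  for (f in seq_len(nrow(mesh$triangles))) {
    idx <- mesh$triangles[f, ]
    nrm[idx, ] <- nrm[idx, ] + matrix(eg$normals[f, ] * eg$areas[f], 3, 3, byrow = TRUE)
  }
  nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), 1e-300)
  e1 <- matrix(0, V, 3); e2 <- matrix(0, V, 3)
  for (vtx in seq_len(V)) {
    n <- nrm[vtx, ]
    ref <- diag(3)[, which.min(abs(n))]
    a <- ref - sum(ref * n) * n
    a <- a / sqrt(sum(a^2))
    e1[vtx, ] <- a
    e2[vtx, ] <- c(n[2] * a[3] - n[3] * a[2],
                   n[3] * a[1] - n[1] * a[3],
                   n[1] * a[2] - n[2] * a[1])
  }
  list(normal = nrm, e1 = e1, e2 = e2)
}

# surface gradients of the three linear shape functions of triangle f:
# grad N_a = n x e_opp / (2 A)
shape_gradients <- function(v1, v2, v3, normal, area) {
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  rbind(cross3(normal, v3 - v2),
        cross3(normal, v1 - v3),
        cross3(normal, v2 - v1)) / (2 * area)
}

#' Assemble the membrane equilibrium system
#'
#' Builds the sparse linear system `A x = b` whose unknowns `x` are the
#' three nodal stress components per vertex and whose rows are the three
#' force-balance equations of each free vertex; `b` carries the
#' consistent pressure load `p * (A_e / 3) * n_e`. The matrix depends on
#' geometry and thickness only, never on the stress.
#'
#' @param mesh A `surface_mesh`.
#' @param load A [load_case()].
#' @param fixed_vertices Vertex indices carrying no balance equations;
#'   defaults to the mesh boundary rings. A closed mesh must supply a
#'   non-empty set.
#' @return List with sparse `A`, dense `b`, the free-vertex index,
#'   per-vertex frames and element geometry (reused by the solver).
#' @export
assemble_equilibrium <- function(mesh, load, fixed_vertices = NULL) {
  eg <- element_geometry(mesh)
  V <- nrow(mesh$vertices)
  if (is.null(fixed_vertices))
    fixed_vertices <- unique(c(mesh$proximal_ring, mesh$distal_ring,
                               unlist(boundary_loops(mesh))))
  if (length(fixed_vertices) == 0)
    stop_aaawall("closed mesh: supply fixed_vertices to anchor the system")
  if (length(fixed_vertices) >= V)
    stop_aaawall("all vertices fixed: nothing to solve")
  free <- setdiff(seq_len(V), fixed_vertices)
  row_of <- integer(V); row_of[free] <- seq_along(free)
  frames <- vertex_frames(mesh, eg)
  h <- load$thickness_cm; p <- load$pressure_ncm2

  FF <- nrow(mesh$triangles)
  # triplets: per element, 3 test vertices x 3 basis vertices x 3
  # components x 3 force directions
  cap <- FF * 81L
  ri <- integer(cap); ci <- integer(cap); xv <- numeric(cap)
  nt <- 0L
  b <- numeric(3L * length(free))
  for (f in seq_len(FF)) {
    tr <- mesh$triangles[f, ]
    G <- shape_gradients(mesh$vertices[tr[1], ], mesh$vertices[tr[2], ],
                         mesh$vertices[tr[3], ], eg$normals[f, ], eg$areas[f])
    coefA <- h * eg$areas[f] / 3
    for (a in 1:3) {
      va <- tr[a]
      if (row_of[va] == 0L) next
      r0 <- 3L * (row_of[va] - 1L)
      b[r0 + 1:3] <- b[r0 + 1:3] + p * eg$areas[f] / 3 * eg$normals[f, ]
      for (bb in 1:3) {
        vb <- tr[bb]
        E1 <- frames$e1[vb, ]; E2 <- frames$e2[vb, ]
        g <- G[a, ]
        # S_b . grad(N_a) for unit s11, s12, s22 in vb's frame
        col_s11 <- E1 * sum(E1 * g)
        col_s12 <- E1 * sum(E2 * g) + E2 * sum(E1 * g)
        col_s22 <- E2 * sum(E2 * g)
        cols <- cbind(col_s11, col_s12, col_s22) * coefA
        c0 <- 3L * (vb - 1L)
        for (kk in 1:3) {
          for (dd in 1:3) {
            if (cols[dd, kk] != 0) {
              nt <- nt + 1L
              ri[nt] <- r0 + dd; ci[nt] <- c0 + kk; xv[nt] <- cols[dd, kk]
            }
          }
        }
      }
    }
  }
  A <- Matrix::sparseMatrix(i = ri[seq_len(nt)], j = ci[seq_len(nt)],
                            x = xv[seq_len(nt)],
                            dims = c(3L * length(free), 3L * V))
  list(A = A, b = b, free = free, fixed = fixed_vertices, frames = frames,
       element_geometry = eg, load = load)
}

# Frobenius-difference smoothing operator: one block of 6 rows per mesh
# edge, expressing vech(S_a - S_b) of the nodal tensors (off-diagonals
# weighted by sqrt(2) so row norms are Frobenius norms).  Each block is
# scaled by h * sqrt(A_edge) * ell0 / len_edge, the discretisation of the
# functional  h^2 * ell0^2 * integral |grad S|^2 dA  with a fixed physical
# smoothing length ell0: stress detail below that scale is damped, and the
# damping of mesh-scale oscillations grows as the mesh refines while the
# bias on smooth fields stays at the (ell0 / R)^2 level.
smoothing_operator <- function(mesh, eg, frames, thickness, ell0) {
  tr <- mesh$triangles
  V <- nrow(mesh$vertices)
  e_all <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  area3 <- rep(eg$areas, 3)
  key <- paste(pmin(e_all[, 1], e_all[, 2]), pmax(e_all[, 1], e_all[, 2]))
  a_edge <- tapply(area3, key, sum) / 3     # area share associated to the edge
  first <- !duplicated(key)
  e <- e_all[first, , drop = FALSE]
  a_edge <- as.numeric(a_edge[key[first]])
  len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                         mesh$vertices[e[, 2], , drop = FALSE])^2))
  # rows of the equilibrium system are nodal forces (force density times
  # vertex area), so the matching discretisation of the smoothing
  # functional weights each edge by its area share (not its square root)
  w <- thickness * a_edge * ell0 / len
  vech6 <- function(S) c(S[1, 1], S[2, 2], S[3, 3],
                         sqrt(2) * S[1, 2], sqrt(2) * S[1, 3], sqrt(2) * S[2, 3])
  Ms <- lapply(seq_len(V), function(v) {
    E1 <- frames$e1[v, ]; E2 <- frames$e2[v, ]
    cbind(vech6(outer(E1, E1)), vech6(outer(E1, E2) + outer(E2, E1)),
          vech6(outer(E2, E2)))
  })
  ne <- nrow(e)
  rows <- integer(ne * 36); cols <- integer(ne * 36); vals <- numeric(ne * 36)
  pos <- 0L
  for (k in seq_len(ne)) {
    r0 <- 6L * (k - 1L)
    for (side in 1:2) {
      v <- e[k, side]; sgn <- if (side == 1) w[k] else -w[k]
      M <- Ms[[v]]
      for (r in 1:6) for (cc in 1:3) {
        pos <- pos + 1L
        rows[pos] <- r0 + r; cols[pos] <- 3L * (v - 1L) + cc
        vals[pos] <- sgn * M[r, cc]
      }
    }
  }
  Matrix::sparseMatrix(i = rows[seq_len(pos)], j = cols[seq_len(pos)],
                       x = vals[seq_len(pos)], dims = c(6L * ne, 3L * V))
}

#' Solve for the membrane wall-stress field
#'
#' Minimises the equilibrium residual of [assemble_equilibrium()] jointly
#' with a smoothing penalty `beta * |L x|^2`, where `L` measures the
#' Frobenius difference of neighbouring nodal stress tensors scaled by a
#' fixed physical smoothing length `ell0` (default 0.1 cm, of the order
#' of the wall thickness -- stress variation below that scale carries no
#' meaning in a membrane model). The penalty suppresses mesh-scale
#' oscillation modes of the inverse problem while biasing smooth fields
#' only at the `(ell0 / R)^2` level; a tiny Frobenius-norm Tikhonov term
#' resolves the remaining rank deficiency (statically indeterminate
#' directions such as uniform axial tension on an open tube take their
#' minimum-norm value, zero). All terms scale identically in pressure
#' and thickness, so stresses are exactly linear in `p` and proportional
#' to `1/h`. Element centroid stresses average the three vertex tensors;
#' principal stresses are the ordered eigenvalues of the centroid tensor
#' restricted to the element tangent plane.
#'
#' @param mesh A `surface_mesh`.
#' @param load A [load_case()].
#' @param fixed_vertices Optional; see [assemble_equilibrium()].
#' @param beta Smoothing weight (default 2, calibrated once against the
#'   cylinder and sphere Laplace-law references).
#' @param ell0 Smoothing length in cm (default 0.1).
#' @param reg_scale Relative Tikhonov weight (default 1e-8; small enough
#'   not to bias determinate stresses, large enough to pin statically
#'   indeterminate directions reproducibly).
#' @param system Optional pre-assembled system from
#'   [assemble_equilibrium()].
#' @param max_residual Error out when the relative equilibrium residual
#'   exceeds this bound (default 0.2; image-derived meshes carry
#'   pixel-scale geometric jitter that inflates the residual without
#'   invalidating the smooth part of the solution).
#' @return A `stress_field`: per-element `sigma11`, `sigma12`, `sigma22`
#'   (contravariant components in the element edge basis), `principal_1
#'   >= principal_2` (N/cm^2), per-element 3x3 `global_tensor`, nodal
#'   tensors, areas, and the relative residual.
#' @export
solve_stress <- function(mesh, load, fixed_vertices = NULL, beta = 2,
                         ell0 = 0.1, reg_scale = 1e-8,
                         system = NULL, max_residual = 0.2) {
  sys <- system %||% assemble_equilibrium(mesh, load, fixed_vertices)
  A <- sys$A; b <- sys$b
  V <- nrow(mesh$vertices)
  AtA <- Matrix::crossprod(A)
  M <- AtA
  if (beta > 0) {
    L <- smoothing_operator(mesh, sys$element_geometry, sys$frames,
                            load$thickness_cm, ell0)
    M <- M + beta * Matrix::crossprod(L)
  }
  lambda <- reg_scale * sum(Matrix::diag(AtA)) / ncol(A)
  D <- Matrix::Diagonal(x = rep(c(1, 2, 1), V))
  K <- M + lambda * D
  rhs <- Matrix::crossprod(A, b)
  x <- Matrix::solve(K, rhs)
  for (it in 1:2) x <- x + Matrix::solve(K, rhs - K %*% x)  # iterative refinement
  x <- as.numeric(x)
  resid <- sqrt(sum((as.numeric(A %*% x) - b)^2))
  rel_resid <- resid / max(sqrt(sum(b^2)), 1e-300)
  if (rel_resid > max_residual)
    stop_aaawall("equilibrium solve failed: relative residual %.3g", rel_resid)

  fr <- sys$frames
  nodal <- array(0, c(3, 3, V))
  for (vtx in seq_len(V)) {
    s11 <- x[3 * vtx - 2]; s12 <- x[3 * vtx - 1]; s22 <- x[3 * vtx]
    E1 <- fr$e1[vtx, ]; E2 <- fr$e2[vtx, ]
    nodal[, , vtx] <- s11 * outer(E1, E1) + s22 * outer(E2, E2) +
      s12 * (outer(E1, E2) + outer(E2, E1))
  }
  FF <- nrow(mesh$triangles)
  eg <- sys$element_geometry
  sig <- matrix(0, FF, 3); pr <- matrix(0, FF, 2)
  gtens <- array(0, c(3, 3, FF))
  for (f in seq_len(FF)) {
    tr <- mesh$triangles[f, ]
    S <- (nodal[, , tr[1]] + nodal[, , tr[2]] + nodal[, , tr[3]]) / 3
    eb <- element_basis(mesh, f)
    # project onto the element tangent plane (drop the small
    # out-of-plane part coming from differing vertex frames)
    n <- eb$normal
    Pn <- diag(3) - outer(n, n)
    S <- Pn %*% S %*% Pn
    gtens[, , f] <- S
    pr[f, ] <- tangent_principal(S, eb)
    sig[f, ] <- contravariant_components(S, eb)
  }
  structure(list(sigma11 = sig[, 1], sigma12 = sig[, 2], sigma22 = sig[, 3],
                 principal_1 = pr[, 1], principal_2 = pr[, 2],
                 global_tensor = gtens, nodal_tensor = nodal,
                 areas = eg$areas, centroids = eg$centroids,
                 residual = rel_resid, lambda = lambda, load = sys$load),
            class = "stress_field")
}

# eigenvalues of S restricted to the element tangent plane, descending
tangent_principal <- function(S, eb) {
  t1 <- eb$g1 / sqrt(sum(eb$g1^2))
  t2v <- eb$g2 - sum(eb$g2 * t1) * t1
  t2 <- t2v / sqrt(sum(t2v^2))
  M <- matrix(c(t1 %*% S %*% t1, t1 %*% S %*% t2,
                t1 %*% S %*% t2, t2 %*% S %*% t2), 2, 2)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  sort(ev, decreasing = TRUE)
}

# contravariant components sigma^{ab} = g^a . S . g^b in the edge basis
contravariant_components <- function(S, eb) {
  gi <- solve(eb$metric)
  gu1 <- gi[1, 1] * eb$g1 + gi[1, 2] * eb$g2
  gu2 <- gi[2, 1] * eb$g1 + gi[2, 2] * eb$g2
  c(as.numeric(gu1 %*% S %*% gu1),
    as.numeric(gu1 %*% S %*% gu2),
    as.numeric(gu2 %*% S %*% gu2))
}

#' Principal stresses from contravariant components
#'
#' Converts contravariant components `sigma^{ab}` in an element's edge
#' basis to the physical tensor `sigma^{ab} g_a (x) g_b`, restricts it to
#' the orthonormal tangent frame, and returns the ordered eigenvalues.
#'
#' @param sigma Length-3 numeric `(sigma11, sigma12, sigma22)`.
#' @param basis An [element_basis()] result.
#' @return Numeric `(principal_1, principal_2)`, descending.
#' @export
principal_stresses <- function(sigma, basis) {
  S <- sigma[1] * outer(basis$g1, basis$g1) +
    sigma[2] * (outer(basis$g1, basis$g2) + outer(basis$g2, basis$g1)) +
    sigma[3] * outer(basis$g2, basis$g2)
  tangent_principal(S, basis)
}

#' Global force balance of a solved stress field
#'
#' Sums the boundary reactions (internal minus external nodal forces at
#' fixed vertices) and compares them with the total pressure load over
#' the free region; for a converged solution they cancel.
#'
#' @param mesh A `surface_mesh`.
#' @param field A `stress_field` from [solve_stress()].
#' @param fixed_vertices As used in the solve (default: boundary rings).
#' @return List with `reaction`, `load`, and `relative_imbalance`.
#' @export
force_balance <- function(mesh, field, fixed_vertices = NULL) {
  load <- field$load
  sys <- assemble_equilibrium(mesh, load, fixed_vertices)
  eg <- sys$element_geometry
  V <- nrow(mesh$vertices)
  fint <- matrix(0, V, 3); fext <- matrix(0, V, 3)
  h <- load$thickness_cm; p <- load$pressure_ncm2
  for (f in seq_len(nrow(mesh$triangles))) {
    tr <- mesh$triangles[f, ]
    G <- shape_gradients(mesh$vertices[tr[1], ], mesh$vertices[tr[2], ],
                         mesh$vertices[tr[3], ], eg$normals[f, ], eg$areas[f])
    S <- (field$nodal_tensor[, , tr[1]] + field$nodal_tensor[, , tr[2]] +
            field$nodal_tensor[, , tr[3]]) / 3
    for (a in 1:3) {
      fint[tr[a], ] <- fint[tr[a], ] + h * eg$areas[f] * as.numeric(S %*% G[a, ])
      fext[tr[a], ] <- fext[tr[a], ] + p * eg$areas[f] / 3 * eg$normals[f, ]
    }
  }
  fixed <- sys$fixed
  reaction <- colSums(fint[fixed, , drop = FALSE] - fext[fixed, , drop = FALSE])
  total_load <- colSums(fext)
  # internal nodal forces sum to zero identically, so reaction must cancel
  # the total load up to the interior equilibrium residual; normalise by
  # the gross pressure load p * total area (the net vector can vanish by
  # symmetry, e.g. on a straight tube)
  gross <- p * sum(eg$areas)
  list(reaction = reaction, load = total_load,
       relative_imbalance = sqrt(sum((reaction + total_load)^2)) /
         max(gross, 1e-300))
}
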