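# Synthetic fusiform-aneurysm phantoms.  These stand in for clinical CTA
# volumes: a tube of baseline radius r0 with a smooth Gaussian bulge to
# rmax, rendered per slice as three intensity zones (bright lumen,
# intermediate wall annulus, dark background) plus additive Gaussian
# noise.  Cross-sections are circles, so every downstream quantity
# (hydraulic diameter, lofted mesh, Laplace-law stress) has an analytic
# reference.  All intensities are arbitrary synthetic units chosen to
# mimic contrast-CTA ordering.

#' Fusiform phantom specification
#'
#' Geometry defaults describe a typical infrarenal aneurysm: 1 cm
#' baseline outer radius dilating to 2.5 cm (5 cm diameter, the elective
#' repair threshold for men) over a 2.5 cm bulge width, sampled on a
#' 96 x 96 grid at 0.8 mm in-plane resolution and 2 mm slice spacing
#' (within the 1-3 mm range typical of clinical CTA).
#'
#' @param r0 Baseline outer radius (cm).
#' @param rmax Bulge radius (cm), `>= r0`.
#' @param z0 Bulge centre slice index (default: middle slice).
#' @param w Bulge Gaussian width (cm).
#' @param n_slices Number of axial slices.
#' @param grid Slice edge length in pixels.
#' @param pixel_size In-plane pixel size (mm/pixel).
#' @param slice_spacing Slice spacing (mm).
#' @param intensities Named or ordered triple `(lumen, wall, background)`
#'   with `lumen > wall > background`.
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param wall_fraction Lumen radius as a fraction of the outer radius
#'   (rendering only; the ground-truth mask is always the full outer
#'   disk).
#' @param seed Integer seed fixing all randomness.
#' @return A `fusiform_spec` object.
#' @export
fusiform_spec <- function(r0 = 1.0, rmax = 2.5, z0 = NULL, w = 2.5,
                          n_slices = 40L, grid = 96L, pixel_size = 0.8,
                          slice_spacing = 2.0,
                          intensities = c(lumen = 300, wall = 150, background = 50),
                          noise_sd = 10, wall_fraction = 0.75, seed = 1L) {
  if (r0 <= 0 || rmax < r0) stop_aaawall("need rmax >= r0 > 0")
  if (is.null(z0)) z0 <- (n_slices + 1) / 2
  if (!(intensities[1] > intensities[2] && intensities[2] > intensities[3]))
    stop_aaawall("intensities must be strictly ordered lumen > wall > background")
  structure(list(r0 = r0, rmax = rmax, z0 = z0, w = w,
                 n_slices = as.integer(n_slices), grid = as.integer(grid),
                 pixel_size = pixel_size, slice_spacing = slice_spacing,
                 intensities = intensities, noise_sd = noise_sd,
                 wall_fraction = wall_fraction, seed = as.integer(seed)),
            class = "fusiform_spec")
}

#' Outer-wall radius profile of the fusiform phantom
#'
#' `r(z) = r0 + (rmax - r0) * exp(-((z - z0) * slice_spacing)^2 / w^2)`
#' with the axial distance in cm.
#'
#' @param spec A [fusiform_spec()].
#' @param z Slice index (may be fractional).
#' @return Outer radius in cm.
#' @export
radius_profile <- function(spec, z) {
  dz_cm <- (z - spec$z0) * spec$slice_spacing / MM_PER_CM
  spec$r0 + (spec$rmax - spec$r0) * exp(-dz_cm^2 / spec$w^2)
}

#' Generate a synthetic fusiform phantom volume
#'
#' Returns the noisy image stack, the per-slice ground-truth outer-wall
#' masks (full outer disk), and the analytic circular contours as a
#' `contour_stack`. Output is fully determined by the spec (including
#' its seed).
#'
#' @param spec A [fusiform_spec()].
#' @param contour_points Sampling resolution of the analytic contours.
#' @return List with `images` (array `grid x grid x n_slices`), `masks`
#'   (list of binary matrices), `contours` (a `contour_stack`), and
#'   `spec`.
#' @export
make_volume <- function(spec, contour_points = 96L) {
  g <- spec$grid
  c0 <- (g + 1) / 2
  r_px_max <- spec$rmax * MM_PER_CM / spec$pixel_size
  if (2 * r_px_max + 4 > g)
    stop_aaawall("bulge radius (%.1f px) exceeds the %d-pixel grid", r_px_max, g)
  xs <- matrix(seq_len(g), g, g) - c0
  ys <- matrix(seq_len(g), g, g, byrow = TRUE) - c0
  rho <- sqrt(xs^2 + ys^2)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  images <- array(0, c(g, g, spec$n_slices))
  masks <- vector("list", spec$n_slices)
  contours <- vector("list", spec$n_slices)
  th <- 2 * pi * (seq_len(contour_points) - 1) / contour_points
  ints <- spec$intensities
  for (z in seq_len(spec$n_slices)) {
    r_cm <- radius_profile(spec, z)
    r_px <- r_cm * MM_PER_CM / spec$pixel_size
    lum_px <- r_px * spec$wall_fraction
    sl <- matrix(ints[3], g, g)
    sl[rho <= r_px] <- ints[2]
    sl[rho <= lum_px] <- ints[1]
    if (spec$noise_sd > 0) sl <- sl + matrix(rnorm(g * g, 0, spec$noise_sd), g, g)
    images[, , z] <- sl
    masks[[z]] <- matrix(as.integer(rho <= r_px), g, g)
    contours[[z]] <- slice_contour(cbind(c0 + r_px * cos(th), c0 + r_px * sin(th)),
                                   pixel_size = spec$pixel_size)
  }
  list(images = images, masks = masks,
       contours = contour_stack(contours, slice_spacing = spec$slice_spacing,
                                pixel_size = spec$pixel_size),
       spec = spec)
}

#' Analytic open-cylinder mesh
#'
#' Cylinder of radius `R` (cm) and length `L` (cm) along z, with
#' `n_theta` vertices per ring and `n_z` rings, outward normals and
#' labelled boundary rings; the Laplace-law reference for the membrane
#' solver (`hoop = p R / h`, axial free).
#'
#' @param R,L Radius and length (cm).
#' @param n_theta Vertices per ring (>= 8).
#' @param n_z Number of rings (>= 2).
#' @return A `surface_mesh`.
#' @export
make_cylinder_mesh <- function(R, L, n_theta = 32L, n_z = 25L) {
  if (R <= 0 || L <= 0) stop_aaawall("R and L must be positive")
  if (n_theta < 8) stop_aaawall("n_theta must be at least 8")
  if (n_z < 2) stop_aaawall("n_z must be at least 2")
  th <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  zs <- seq(0, L, length.out = n_z)
  verts <- do.call(rbind, lapply(zs, function(z) cbind(R * cos(th), R * sin(th), z)))
  m <- n_theta
  tris <- matrix(0L, 0, 3)
  for (j in seq_len(n_z - 1)) {
    a <- (j - 1) * m + seq_len(m); b <- j * m + seq_len(m)
    an <- a[c(2:m, 1)]; bn <- b[c(2:m, 1)]
    tris <- rbind(tris,
                  cbind(a, an, bn),
                  cbind(a, bn, b))
  }
  orient_outward(surface_mesh(verts, tris, proximal_ring = seq_len(m),
                              distal_ring = (n_z - 1) * m + seq_len(m)))
}

#' Analytic icosphere mesh
#'
#' Icosahedron subdivided `subdivisions` times with vertices projected to
#' radius `R`; the Laplace-law reference for a closed membrane
#' (`sigma1 = sigma2 = p R / (2h)`).
#'
#' @param R Radius (cm).
#' @param subdivisions Number of 4-way subdivisions (default 3).
#' @return A closed `surface_mesh` (no boundary rings).
#' @export
make_sphere_mesh <- function(R, subdivisions = 3L) {
  if (R <= 0) stop_aaawall("R must be positive")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  proj <- function(m) m * R / sqrt(rowSums(m^2))
  v <- proj(v)
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      p <- (v[i, ] + v[j, ]) / 2
      p <- p * R / sqrt(sum(p^2))
      v <<- rbind(v, p)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  mesh <- surface_mesh(v, f)
  # outward orientation: flip winding where the normal opposes the radius
  eg <- element_geometry(mesh)
  flip <- rowSums(eg$normals * eg$centroids) < 0
  mesh$triangles[flip, ] <- mesh$triangles[flip, c(1, 3, 2)]
  mesh
}
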