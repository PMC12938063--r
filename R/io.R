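# Plain-text mesh and image I/O.  Meshes use ASCII STL / PLY for
# geometry and legacy ASCII VTK for geometry plus per-cell stress
# scalars; volumes round-trip as NIfTI (with mm spacing in the header)
# or per-slice PNG with a JSON metadata sidecar.

#' Write a mesh as ASCII STL
#'
#' @param mesh A `surface_mesh`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  eg <- element_geometry(mesh)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("solid aaawall", con)
  v <- mesh$vertices; tr <- mesh$triangles
  for (f in seq_len(nrow(tr))) {
    writeLines(sprintf("facet normal %.9g %.9g %.9g", eg$normals[f, 1],
                       eg$normals[f, 2], eg$normals[f, 3]), con)
    writeLines("  outer loop", con)
    for (k in 1:3)
      writeLines(sprintf("    vertex %.9g %.9g %.9g", v[tr[f, k], 1],
                         v[tr[f, k], 2], v[tr[f, k], 3]), con)
    writeLines(c("  endloop", "endfacet"), con)
  }
  writeLines("endsolid aaawall", con)
  invisible(path)
}

#' Read an ASCII STL mesh
#'
#' Vertices are de-duplicated exactly; boundary rings are recovered from
#' the boundary loops (lowest mean z first, the proximal convention).
#'
#' @param path STL path.
#' @return A `surface_mesh`.
#' @export
read_stl <- function(path) {
  lines <- readLines(path)
  vlines <- grep("^\\s*vertex", lines, value = TRUE)
  coords <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                                  function(x) as.numeric(x[2:4])))
  key <- apply(coords, 1, paste, collapse = "|")
  uk <- !duplicated(key)
  verts <- coords[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  tris <- matrix(idx, ncol = 3, byrow = TRUE)
  mesh <- surface_mesh(verts, tris)
  loops <- boundary_loops(mesh)
  if (length(loops) == 2) {
    mz <- vapply(loops, function(l) mean(verts[l, 3]), numeric(1))
    mesh$proximal_ring <- loops[[which.min(mz)]]
    mesh$distal_ring <- loops[[which.max(mz)]]
  }
  mesh
}

#' Write a mesh as ASCII PLY
#'
#' @param mesh A `surface_mesh`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices; tr <- mesh$triangles
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(tr)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", tr[, 1] - 1, tr[, 2] - 1, tr[, 3] - 1), con)
  invisible(path)
}

#' Write a mesh (and optional stress field) as legacy ASCII VTK
#'
#' Cell data arrays `sigma11`, `sigma12`, `sigma22`, `principal_1`,
#' `principal_2` (N/cm^2) are attached when a `stress_field` is given.
#'
#' @param mesh A `surface_mesh`.
#' @param path Output path.
#' @param field Optional `stress_field`.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, field = NULL) {
  v <- mesh$vertices; tr <- mesh$triangles
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "aaawall surface mesh", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", nrow(v))), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(tr), 4 * nrow(tr)), con)
  writeLines(sprintf("3 %d %d %d", tr[, 1] - 1, tr[, 2] - 1, tr[, 3] - 1), con)
  if (!is.null(field)) {
    writeLines(sprintf("CELL_DATA %d", nrow(tr)), con)
    for (nm in c("sigma11", "sigma12", "sigma22", "principal_1", "principal_2")) {
      writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", field[[nm]]), con)
    }
  }
  invisible(path)
}

#' Write / read an image stack as NIfTI
#'
#' The in-plane pixel size and slice spacing travel in the NIfTI pixdim
#' header fields (mm).
#'
#' @param images Array `(x, y, slice)`.
#' @param path `.nii` or `.nii.gz` path.
#' @param pixel_size,slice_spacing mm.
#' @return `write_volume_nifti` returns `path` invisibly;
#'   `read_volume_nifti` a list `(images, pixel_size, slice_spacing)`.
#' @export
write_volume_nifti <- function(images, path, pixel_size, slice_spacing) {
  img <- RNifti::asNifti(images)
  RNifti::pixdim(img) <- c(pixel_size, pixel_size, slice_spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  list(images = unclass(as.array(img)), pixel_size = pd[1], slice_spacing = pd[3])
}

#' Write / read per-slice masks as PNG + JSON metadata
#'
#' Slice `i` goes to `slice_%03d.png`; `meta.json` records
#' `pixel_size_mm` and `slice_spacing_mm`.
#'
#' @param masks List of binary matrices.
#' @param dir Output directory (created).
#' @param pixel_size,slice_spacing mm.
#' @return `write_mask_pngs` returns `dir` invisibly; `read_mask_pngs` a
#'   list `(masks, pixel_size, slice_spacing)`.
#' @export
write_mask_pngs <- function(masks, dir, pixel_size, slice_spacing) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(masks))
    png::writePNG(matrix(as.numeric(masks[[i]]), nrow(masks[[i]])),
                  file.path(dir, sprintf("slice_%03d.png", i)))
  jsonlite::write_json(list(pixel_size_mm = pixel_size,
                            slice_spacing_mm = slice_spacing,
                            n_slices = length(masks)),
                       file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_mask_pngs
#' @export
read_mask_pngs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^slice_\\d+\\.png$", full.names = TRUE))
  masks <- lapply(files, function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3) m <- m[, , 1]
    matrix(as.integer(m > 0.5), nrow(m), ncol(m))
  })
  list(masks = masks, pixel_size = meta$pixel_size_mm,
       slice_spacing = meta$slice_spacing_mm)
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint is self-describing: it stores the full
#' [unet_config()] alongside the parameter arrays.
#'
#' @param model A `unet_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `save_checkpoint` returns `path` invisibly;
#'   `load_checkpoint` the `unet_model`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "unet_model")) stop_aaawall("not a unet_model checkpoint")
  model
}
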