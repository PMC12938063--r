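# End-to-end orchestration: phantom -> (segment) -> refine -> mesh ->
# stress -> summaries, with per-stage artifacts and a manifest.  Every
# stage is also callable on its own through the exported module
# functions; the pipeline only chains them.

#' Pipeline configuration
#'
#' Stage toggles must form a prefix-closed chain (e.g. `stress` requires
#' `mesh`). When `segment` is off, the ground-truth masks are carried
#' forward (the "ground truth" arm of the framework); when `refine` is
#' off, contours are taken from the masks directly.
#'
#' @param stages Character subset of
#'   `c("segment", "refine", "mesh", "stress", "metrics")`.
#' @param phantom A [fusiform_spec()] providing the input volume.
#' @param load A [load_case()].
#' @param nurbs List of NURBS settings `(n_points, degree, mode)`.
#' @param points_per_ring Mesh lofting resolution.
#' @param model Optional trained `unet_model` (required for `segment`).
#' @param out_dir Optional artifact directory; `NULL` keeps everything
#'   in memory.
#' @param seed Integer seed recorded in the manifest.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(stages = c("refine", "mesh", "stress", "metrics"),
                            phantom = fusiform_spec(),
                            load = load_case(),
                            nurbs = list(n_points = 24L, degree = 3L,
                                         mode = "approximate"),
                            points_per_ring = 48L,
                            model = NULL, out_dir = NULL, seed = 1L) {
  all_stages <- c("segment", "refine", "mesh", "stress", "metrics")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if ("stress" %in% stages && !("mesh" %in% stages))
    stop_aaawall("stage 'stress' requires stage 'mesh'")
  if ("metrics" %in% stages && !("stress" %in% stages) && !("segment" %in% stages))
    stop_aaawall("stage 'metrics' requires 'stress' or 'segment'")
  if ("segment" %in% stages && is.null(model))
    stop_aaawall("stage 'segment' requires a trained model")
  structure(list(stages = stages, phantom = phantom, load = load,
                 nurbs = nurbs, points_per_ring = points_per_ring,
                 model = model, out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the analysis pipeline on a phantom case
#'
#' Generates the phantom volume, then runs the enabled stages in order:
#' segmentation (model prediction; otherwise ground-truth masks),
#' NURBS refinement of each mask, contour-stack mesh lofting, membrane
#' stress solve, and summary metrics. Artifacts are written under
#' `config$out_dir` when given (NIfTI volume, mask PNGs, contour CSV,
#' STL/VTK meshes, JSON summaries) together with a manifest recording
#' parameters, seed and md5 hashes of every written file.
#'
#' @param config A [pipeline_config()].
#' @return A case bundle: `masks`, `contours`, `mesh`, `stress`
#'   (`stress_field`), `stress_summary`, `seg_report` (when masks were
#'   predicted), `diameter` (max hydraulic diameter), and `manifest`.
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_aaawall("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  out <- list()
  artifacts <- character(0)
  od <- config$out_dir
  if (!is.null(od)) dir.create(od, recursive = TRUE, showWarnings = FALSE)
  emit <- function(path) artifacts <<- c(artifacts, path)

  vol <- stage("phantom", make_volume(config$phantom))
  spc <- config$phantom
  if (!is.null(od)) {
    emit(write_volume_nifti(vol$images, file.path(od, "volume.nii.gz"),
                            spc$pixel_size, spc$slice_spacing))
    emit(write_mask_pngs(vol$masks, file.path(od, "truth_masks"),
                         spc$pixel_size, spc$slice_spacing))
  }

  masks <- vol$masks
  if ("segment" %in% config$stages) {
    masks <- stage("segment", predict_masks(config$model, vol$images))
    out$seg_report <- stage("segment",
                            evaluate_masks(masks, vol$masks, spc$pixel_size))
    if (!is.null(od)) {
      emit(write_mask_pngs(masks, file.path(od, "pred_masks"),
                           spc$pixel_size, spc$slice_spacing))
      p <- file.path(od, "seg_report.csv")
      write.csv(out$seg_report$per_slice, p, row.names = FALSE)
      emit(p)
    }
  }
  out$masks <- masks

  if ("refine" %in% config$stages) {
    nb <- config$nurbs
    contours <- stage("refine", lapply(masks, function(m) {
      ct <- mask_to_contour(m, pixel_size = spc$pixel_size)
      cv <- fit_contour(ct, n_points = nb$n_points, degree = nb$degree,
                        mode = nb$mode)
      ts <- (seq_len(10L * nb$n_points) - 1) / (10L * nb$n_points)
      slice_contour(evaluate_curve(cv, ts), pixel_size = spc$pixel_size)
    }))
    out$contours <- contour_stack(contours, spc$slice_spacing, spc$pixel_size)
  } else {
    out$contours <- stage("contours", contour_stack(
      lapply(masks, mask_to_contour, pixel_size = spc$pixel_size),
      spc$slice_spacing, spc$pixel_size))
  }
  if (!is.null(od)) emit(write_contours_csv(out$contours, file.path(od, "contours.csv")))
  out$diameter <- max_hydraulic_diameter(out$contours)

  if ("mesh" %in% config$stages) {
    out$mesh <- stage("mesh", loft_mesh(out$contours, config$points_per_ring))
    if (!is.null(od)) emit(write_stl(out$mesh, file.path(od, "mesh.stl")))
  }

  if ("stress" %in% config$stages) {
    if (is.null(out$mesh)) stop_aaawall("stage 'stress' has no upstream mesh")
    out$stress <- stage("stress", solve_stress(out$mesh, config$load))
    out$stress_summary <- stress_summary(out$stress)
    if (!is.null(od)) {
      emit(write_vtk(out$mesh, file.path(od, "stress.vtk"), out$stress))
      p <- file.path(od, "stress_summary.json")
      jsonlite::write_json(unclass(out$stress_summary), p, auto_unbox = TRUE,
                           digits = NA)
      emit(p)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("aaawall")),
    seed = config$seed,
    stages = config$stages,
    phantom = unclass(config$phantom),
    load = unclass(config$load),
    nurbs = config$nurbs,
    points_per_ring = config$points_per_ring)
  if (!is.null(od)) {
    files <- sort(unlist(lapply(artifacts, function(a)
      if (dir.exists(a)) list.files(a, full.names = TRUE, recursive = TRUE) else a)))
    manifest$artifacts <- lapply(files, function(f)
      list(path = sub(paste0("^", od, "/?"), "", f),
           md5 = unname(tools::md5sum(f))))
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out$manifest <- manifest
  out
}
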