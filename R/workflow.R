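# End-to-end workflow: volume (MRC) or surface (.vtp) input -> surface graph ->
# optional border removal -> vector-voting normals -> curvature estimation ->
# .vtp output with all per-triangle arrays plus a JSON run manifest.

#' Workflow configuration
#'
#' Bundles and validates all parameters of [run_workflow()].
#'
#' @param membrane path to the membrane segmentation (MRC) — required for volume
#'   input, ignored for surface input.
#' @param lumen path to the filled-lumen segmentation (MRC); required with
#'   `membrane` unless `fill_membrane = TRUE`.
#' @param surface path to an input surface (.vtp); skips surface generation.
#' @param algorithm `"AVV"` (default), `"RVV"`, `"NVV"` or `"SSVV"`.
#' @param rh neighborhood scale `radius_hit`, `> 0`, in `units`.
#' @param units `"voxel"` or `"nm"`; with `"nm"`, coordinates are scaled by the
#'   voxel size and curvatures come out in 1/nm.
#' @param voxel_size voxel edge length in nm (overrides the MRC header).
#' @param exclude_borders geodesic border-exclusion distance (same units).
#' @param smoothing_sigma,mask_dist surface-generation parameters (voxels).
#' @param fill_membrane emulate compartment input by flood-filling the membrane.
#' @param seed integer seed (only stochastic generators consume it).
#' @param output output .vtp path.
#' @param manifest output JSON manifest path (default: output + ".json").
#' @return a `run_config` list.
#' @export
run_config <- function(membrane = NULL, lumen = NULL, surface = NULL,
                       algorithm = c("AVV", "RVV", "NVV", "SSVV"), rh = 10,
                       units = c("voxel", "nm"), voxel_size = NULL,
                       exclude_borders = 0, smoothing_sigma = 1, mask_dist = 3,
                       fill_membrane = FALSE, seed = 1L,
                       output = "surface_curvature.vtp", manifest = NULL) {
  algorithm <- match.arg(algorithm)
  units <- match.arg(units)
  stopifnot(rh > 0, exclude_borders >= 0)
  if (units == "nm" && is.null(voxel_size) && is.null(surface))
    stopifnot(TRUE) # voxel size may still come from the MRC header
  if (is.null(surface) && is.null(membrane))
    stop("either a surface (.vtp) or a membrane segmentation (MRC) is required")
  if (!is.null(membrane) && is.null(lumen) && !fill_membrane && is.null(surface))
    stop(paste("volume input needs a compartment segmentation:",
               "provide a filled lumen mask or set fill_membrane = TRUE"))
  structure(list(
    membrane = membrane, lumen = lumen, surface = surface,
    algorithm = algorithm, rh = rh, units = units, voxel_size = voxel_size,
    exclude_borders = exclude_borders, smoothing_sigma = smoothing_sigma,
    mask_dist = mask_dist, fill_membrane = fill_membrane, seed = seed,
    output = output,
    manifest = if (is.null(manifest)) paste0(output, ".json") else manifest
  ), class = "run_config")
}

#' Run the full curvature-estimation workflow
#'
#' Executes, in order: surface generation (volume input only), surface-graph
#' construction, optional border filtering, vector-voting normal estimation,
#' the chosen curvature algorithm and the combined measures, then writes the
#' result surface (.vtp, all per-triangle arrays) and a JSON manifest with the
#' parameters and counts. Output files are only written after all stages have
#' succeeded.
#'
#' @param config a `run_config`.
#' @return the result `triangle_mesh`, invisibly; side effects: `.vtp` and
#'   manifest files.
#' @export
run_workflow <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  voxel_size <- config$voxel_size
  if (!is.null(config$surface)) {
    mesh <- stage("read surface", read_vtp(config$surface))
    if (is.null(voxel_size)) voxel_size <- 1
  } else {
    membrane <- stage("read membrane", read_mrc(config$membrane,
                                                voxel_size = config$voxel_size))
    if (is.null(voxel_size)) voxel_size <- membrane$voxel_size
    mesh <- if (config$fill_membrane && is.null(config$lumen)) {
      stage("surface generation",
            membrane_to_surface(membrane, config$smoothing_sigma,
                                config$mask_dist))
    } else {
      lumen <- stage("read lumen", read_mrc(config$lumen,
                                            voxel_size = config$voxel_size))
      stage("surface generation",
            compartment_to_surface(membrane, lumen, config$smoothing_sigma,
                                   config$mask_dist))
    }
  }

  scale <- if (config$units == "nm") voxel_size else 1
  if (scale != 1)
    mesh <- triangle_mesh(mesh$vertices * scale, mesh$faces,
                          normals = mesh$normals)

  graph <- stage("surface graph", build_surface_graph(mesh))
  n_border <- sum(graph$border)
  if (config$exclude_borders > 0 && n_border > 0) {
    mesh <- stage("border removal",
                  filter_borders(mesh, graph, config$exclude_borders))
    graph <- stage("surface graph", build_surface_graph(mesh))
  }
  mesh <- stage("normal estimation", estimate_normals(mesh, graph, config$rh))
  mesh <- stage("curvature estimation",
                estimate_curvature(mesh, graph, config$rh,
                                   algorithm = config$algorithm))

  stage("write output", write_vtp(mesh, config$output))
  manifest <- list(
    parameters = config[c("algorithm", "rh", "units", "exclude_borders",
                          "smoothing_sigma", "mask_dist", "seed")],
    voxel_size = voxel_size,
    curvature_unit_scale = 1 / scale,
    n_triangles = nrow(mesh$faces),
    n_border = n_border,
    n_failed = sum(mesh$data$cv_failed),
    package_version = as.character(utils::packageVersion("curvomesh"))
  )
  jsonlite::write_json(manifest, config$manifest, auto_unbox = TRUE,
                       digits = NA)
  invisible(mesh)
}
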