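# Signed single-layer surface extraction from a compartment segmentation: the
# membrane mask and the filled lumen mask are joined, lightly Gaussian-smoothed
# (sub-voxel precision), isosurfaced at the binary half-maximum, and the surface
# is masked back to the membrane region. The remaining ~mask_dist collar at open
# borders is meant to be removed afterwards with filter_borders() (the final
# cleaning step of the workflow).

#' Extract a surface from a compartment segmentation
#'
#' Joins the membrane and filled-lumen masks, smooths the binary volume with a
#' Gaussian kernel (`smoothing_sigma`, default 1 voxel), extracts the 0.5
#' isosurface and keeps only triangles whose centroid lies within `mask_dist`
#' voxels of a membrane voxel. Normals point from the surface into the filled
#' volume (inwards for a convex compartment).
#'
#' @param membrane a `segmentation_volume` (membrane mask).
#' @param lumen a `segmentation_volume` (filled compartment interior); its
#'   dimensions must match the membrane mask and it must be non-empty.
#' @param smoothing_sigma Gaussian sigma in voxels (0 disables smoothing).
#' @param mask_dist masking distance threshold in voxels (bridges small holes).
#' @return a `triangle_mesh` in voxel units.
#' @export
compartment_to_surface <- function(membrane, lumen, smoothing_sigma = 1,
                                   mask_dist = 3) {
  stopifnot(inherits(membrane, "segmentation_volume"))
  if (is.null(lumen) || !inherits(lumen, "segmentation_volume") ||
        sum(lumen$data) == 0)
    stop("compartment segmentation requires a non-empty filled lumen mask")
  if (!all(dim(membrane$data) == dim(lumen$data)))
    stop("membrane and lumen masks must have matching dimensions")
  joined <- pmax(membrane$data, lumen$data)
  if (sum(joined) == 0) stop("empty joined volume")
  field <- gaussian_smooth_volume(joined, smoothing_sigma)
  mesh <- isosurface(field, level = 0.5)
  mask_surface(mesh, membrane, mask_dist)
}

#' Fill a membrane segmentation and extract its surface
#'
#' Emulates the membrane-segmentation input path by morphologically filling the
#' membrane mask (flood fill of the outside background; everything not reached
#' is inside) and running [compartment_to_surface()] on the result. Requires a
#' membrane that actually encloses a volume.
#'
#' @inheritParams compartment_to_surface
#' @return a `triangle_mesh` in voxel units.
#' @export
membrane_to_surface <- function(membrane, smoothing_sigma = 1, mask_dist = 3) {
  stopifnot(inherits(membrane, "segmentation_volume"))
  filled <- fill_mask(membrane$data)
  lumen <- segmentation_volume(pmax(filled - membrane$data, 0),
                               voxel_size = membrane$voxel_size)
  compartment_to_surface(membrane, lumen, smoothing_sigma, mask_dist)
}

# 6-connected flood fill from the volume boundary; returns mask with the
# enclosed interior (and the membrane itself) set to 1
fill_mask <- function(data) {
  d <- dim(data)
  outside <- array(FALSE, d)
  frontier <- which(data == 0 &
                      (slice.index(data, 1) %in% c(1, d[1]) |
                         slice.index(data, 2) %in% c(1, d[2]) |
                         slice.index(data, 3) %in% c(1, d[3])))
  outside[frontier] <- TRUE
  repeat {
    if (length(frontier) == 0L) break
    idx <- arrayInd(frontier, d)
    nxt <- integer(0)
    for (axis in 1:3) {
      for (dir in c(-1L, 1L)) {
        nb <- idx
        nb[, axis] <- nb[, axis] + dir
        ok <- nb[, axis] >= 1L & nb[, axis] <= d[axis]
        lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] +
          (nb[ok, 3] - 1L) * d[1] * d[2]
        lin <- lin[!outside[lin] & data[lin] == 0]
        if (length(lin) > 0) {
          outside[lin] <- TRUE
          nxt <- c(nxt, lin)
        }
      }
    }
    frontier <- unique(nxt)
  }
  array(as.numeric(!outside), d)
}

#' Mask a surface with a segmentation
#'
#' Keeps the triangles whose centroid lies within `dist` voxels (Euclidean, via
#' nearest foreground voxel) of the mask.
#'
#' @param mesh a `triangle_mesh` in voxel units.
#' @param mask a `segmentation_volume`.
#' @param dist distance threshold in voxels, `>= 0`.
#' @return the masked `triangle_mesh`.
#' @export
mask_surface <- function(mesh, mask, dist) {
  stopifnot(inherits(mesh, "triangle_mesh"), dist >= 0)
  data <- if (inherits(mask, "segmentation_volume")) mask$data else mask
  if (sum(data > 0) == 0) stop("empty mask")
  d <- distance_to_mask(mesh$centroids, data)
  keep <- d <= dist
  if (!any(keep)) stop("all triangles removed by mask")
  subset_triangles(mesh, keep)
}
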