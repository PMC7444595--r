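# Triangle-mesh data model. All per-triangle quantities (centroid, area, oriented
# normal, estimation results) live alongside the vertex/face arrays; coordinates are
# in the units of the input (voxels by default).

#' Construct a triangle mesh
#'
#' Creates an oriented triangle mesh from a vertex array and a face index array.
#' Per-triangle centroids, areas and unit normals are computed on construction.
#' By convention normals point *inwards* on a convex closed surface; generators
#' in this package establish that orientation and `triangle_mesh()` preserves the
#' winding it is given (normal = right-hand rule on the face winding), unless
#' explicit `normals` are supplied.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates.
#' @param faces integer matrix, m x 3, 1-based vertex indices; each face must
#'   reference three distinct existing vertices.
#' @param normals optional m x 3 matrix of per-triangle normals; if supplied they
#'   are normalized and override the winding normals (winding is then flipped to
#'   agree with them).
#' @return an object of class `triangle_mesh` with elements `vertices`, `faces`,
#'   `centroids`, `areas`, `normals` and a per-triangle attribute table `data`
#'   (tibble, filled by estimators).
#' @export
triangle_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) == 0L) stop("empty mesh")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
            faces[, 2] == faces[, 3]))
    stop("faces must reference three distinct vertices")

  p1 <- vertices[faces[, 1], , drop = FALSE]
  p2 <- vertices[faces[, 2], , drop = FALSE]
  p3 <- vertices[faces[, 3], , drop = FALSE]
  centroids <- (p1 + p2 + p3) / 3
  cr <- row_cross(p2 - p1, p3 - p1)
  crn <- row_norms(cr)
  areas <- crn / 2

  if (is.null(normals)) {
    nrm <- cr / pmax(crn, .Machine$double.eps)
  } else {
    nrm <- as.matrix(normals)
    if (!all(dim(nrm) == c(nrow(faces), 3L)))
      stop("normals must be an m x 3 matrix")
    nrm <- nrm / pmax(row_norms(nrm), .Machine$double.eps)
    # flip winding where it disagrees with the supplied normal
    flip <- rowSums(cr * nrm) < 0
    if (any(flip)) faces[flip, 2:3] <- faces[flip, 3:2]
  }

  structure(
    list(
      vertices = vertices,
      faces = faces,
      centroids = centroids,
      areas = areas,
      normals = nrm,
      data = tibble::tibble(.rows = nrow(faces))
    ),
    class = "triangle_mesh"
  )
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf(
    "<triangle_mesh> %d vertices, %d triangles (total area %.4g)\n",
    nrow(x$vertices), nrow(x$faces), sum(x$areas)
  ))
  if (ncol(x$data) > 0)
    cat("  per-triangle attributes:", paste(names(x$data), collapse = ", "), "\n")
  invisible(x)
}

#' Number of triangles in a mesh
#' @param mesh a `triangle_mesh`.
#' @return integer count of faces.
#' @export
n_triangles <- function(mesh) nrow(mesh$faces)

#' Per-triangle attribute table of a mesh
#'
#' Returns one row per triangle with centroid coordinates, area and normal
#' components, together with any estimation results stored on the mesh
#' (e.g. `kappa_1`, `kappa_2`, `shape_index` after [estimate_curvature()]).
#'
#' @param x a `triangle_mesh`.
#' @param ... unused.
#' @return a tibble with `n_triangles(x)` rows.
#' @method as_tibble triangle_mesh
#' @export
as_tibble.triangle_mesh <- function(x, ...) {
  mesh <- x
  base <- tibble::tibble(
    triangle = seq_len(nrow(mesh$faces)),
    x = mesh$centroids[, 1], y = mesh$centroids[, 2], z = mesh$centroids[, 3],
    area = mesh$areas,
    nx = mesh$normals[, 1], ny = mesh$normals[, 2], nz = mesh$normals[, 3]
  )
  if (ncol(mesh$data) > 0) base <- tibble::as_tibble(cbind(base, mesh$data))
  base
}

#' Keep a subset of triangles
#'
#' Subsets the faces (and per-triangle attributes) of a mesh, dropping vertices
#' that become unreferenced.
#'
#' @param mesh a `triangle_mesh`.
#' @param keep logical or integer index over triangles.
#' @return a `triangle_mesh` with the retained triangles.
#' @export
subset_triangles <- function(mesh, keep) {
  idx <- seq_len(nrow(mesh$faces))[keep]
  if (length(idx) == 0L) stop("surface fully removed")
  faces <- mesh$faces[idx, , drop = FALSE]
  used <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  out <- triangle_mesh(mesh$vertices[used, , drop = FALSE],
                       matrix(remap[faces], ncol = 3L),
                       normals = mesh$normals[idx, , drop = FALSE])
  out$data <- mesh$data[idx, , drop = FALSE]
  out
}

# mean edge length over all faces (each face contributes its three edges)
mesh_mean_edge <- function(mesh) {
  p1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  p2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  p3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  mean(c(row_norms(p2 - p1), row_norms(p3 - p2), row_norms(p1 - p3)))
}

# area below this threshold => triangle is degenerate: it keeps a graph vertex
# but casts no votes
DEGENERATE_AREA <- 1e-12

row_norms <- function(m) sqrt(rowSums(m * m))

row_cross <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

unit_rows <- function(m) m / pmax(row_norms(m), .Machine$double.eps)
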