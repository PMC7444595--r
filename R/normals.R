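# Tensor-voting estimation of robust per-triangle normals (the "VV" step shared
# by all curvature algorithm variants). Each neighbor casts a normal vote obtained
# by transporting its normal along the shortest circular arc joining the two
# centroids; votes are accumulated as weighted outer products and the dominant
# eigenvector, re-signed against the original oriented normal, is the estimate.

#' Geodesic neighborhood parameters from the radius_hit scale
#'
#' `radius_hit` (rh) approximates the inverse of the highest curvature that can
#' be estimated reliably. The maximum geodesic reach is a quarter circle of
#' radius rh, `g_max = pi * rh / 2`, and the exponential decay constant of the
#' vote weights satisfies `3 * sigma = g_max`.
#'
#' @param rh neighborhood scale (length units of the mesh), `> 0`.
#' @return a list with `rh`, `g_max` and `sigma`.
#' @export
neighborhood_params <- function(rh) {
  stopifnot(is.numeric(rh), length(rh) == 1L, rh > 0)
  g_max <- pi * rh / 2
  list(rh = rh, g_max = g_max, sigma = g_max / 3)
}

#' Normal vote of one neighboring triangle
#'
#' Transports the neighbor's normal `n_ci` (at centroid `c_i`) along the
#' shortest circular arc to the receiving centroid `v`:
#' `n_i = n_ci + 2 * cos(theta_i) * u`, with `u = (c_i - v)/||c_i - v||` and
#' `cos(theta_i) = -n_ci . u`. This is a Householder reflection, so the vote has
#' unit length.
#'
#' @param n_ci unit normal of the voting triangle.
#' @param v receiving centroid.
#' @param c_i voting centroid (must differ from `v`).
#' @return a unit 3-vector.
#' @export
normal_vote <- function(n_ci, v, c_i) {
  d <- c_i - v
  len <- sqrt(sum(d * d))
  if (len < 1e-12) stop("coincident centroids")
  u <- d / len
  ct <- -sum(n_ci * u)
  n_ci + 2 * ct * u
}

#' Collect normal votes for one triangle
#'
#' Accumulates the weighted covariance sum `V_v = sum_i w_i n_i n_i^T` over all
#' non-degenerate triangles within geodesic distance `g_max` of triangle `v`,
#' with weights `w_i = (a_i / a_max) * exp(-g_i / sigma)`; `a_max` is the
#' largest triangle area on the whole surface.
#'
#' @param mesh a `triangle_mesh`.
#' @param graph its `surface_graph`.
#' @param v receiving triangle index.
#' @param params result of [neighborhood_params()].
#' @return a list with the 3x3 matrix `V`, the vote weights `w` and the
#'   neighbor indices `triangle`.
#' @export
collect_normal_votes <- function(mesh, graph, v, params) {
  nb <- geodesic_neighborhood(graph, v, params$g_max)
  acc <- normal_vote_matrix(mesh, v, nb$triangle, nb$geodesic,
                            params$sigma, max(mesh$areas))
  if (is.null(acc)) stop("isolated vertex")
  acc
}

# vectorized vote accumulation for one receiving triangle; returns NULL when no
# admissible vote exists
normal_vote_matrix <- function(mesh, v, nb, g, sigma, a_max) {
  ok <- mesh$areas[nb] > DEGENERATE_AREA
  nb <- nb[ok]; g <- g[ok]
  if (length(nb) == 0L) return(NULL)
  d <- mesh$centroids[nb, , drop = FALSE] -
    matrix(mesh$centroids[v, ], length(nb), 3, byrow = TRUE)
  len <- row_norms(d)
  keep <- len > 1e-12
  nb <- nb[keep]; g <- g[keep]; d <- d[keep, , drop = FALSE]; len <- len[keep]
  if (length(nb) == 0L) return(NULL)
  u <- d / len
  nrm <- mesh$normals[nb, , drop = FALSE]
  ct <- -rowSums(nrm * u)
  votes <- nrm + 2 * ct * u
  w <- (mesh$areas[nb] / a_max) * exp(-g / sigma)
  list(V = crossprod(votes * sqrt(w)), w = w, triangle = nb)
}

#' Orient the dominant eigenvector of a normal-vote accumulator
#'
#' The estimated normal is the unit eigenvector of the largest eigenvalue of
#' `V_v`; its sign (lost in the outer products) is recovered from the original
#' oriented normal by maximizing the dot product.
#'
#' @param acc result of [collect_normal_votes()] (or any list with a 3x3 `V`).
#' @param original_normal the triangle's original unit normal.
#' @return a unit 3-vector.
#' @export
estimate_normal <- function(acc, original_normal) {
  V <- acc$V
  if (all(V == 0)) stop("zero vote matrix")
  e <- eigen(V, symmetric = TRUE)
  n <- e$vectors[, 1]
  if (sum(n * original_normal) < 0) n <- -n
  n
}

#' Estimate robust normals for every triangle (Vector Voting)
#'
#' Runs the normal tensor-voting step over the whole mesh: for each triangle,
#' votes from its geodesic neighborhood are accumulated and the re-signed
#' dominant eigenvector becomes the estimated normal `n_v`. Triangles with an
#' empty neighborhood keep their original normal and are flagged.
#'
#' @param mesh a `triangle_mesh`.
#' @param graph its `surface_graph`.
#' @param rh neighborhood scale `radius_hit` (mesh units).
#' @return `mesh` with columns `n_v_x`, `n_v_y`, `n_v_z` and logical
#'   `vv_isolated` added to its per-triangle `data`.
#' @export
estimate_normals <- function(mesh, graph, rh) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(graph, "surface_graph"),
            nrow(mesh$faces) == graph$n)
  params <- neighborhood_params(rh)
  res <- cpp_vv_normals(mesh$centroids, mesh$normals, mesh$areas,
                        graph$edges$i, graph$edges$j, graph$edges$w,
                        params$g_max, params$sigma, max(mesh$areas))
  out <- res$normals
  mesh$data$n_v_x <- out[, 1]
  mesh$data$n_v_y <- out[, 2]
  mesh$data$n_v_z <- out[, 3]
  mesh$data$vv_isolated <- res$isolated
  mesh
}

# fetch the estimated normals matrix, failing if VV has not been run
estimated_normals <- function(mesh) {
  if (!all(c("n_v_x", "n_v_y", "n_v_z") %in% names(mesh$data)))
    stop("estimated normals not available; run estimate_normals() first")
  cbind(mesh$data$n_v_x, mesh$data$n_v_y, mesh$data$n_v_z)
}
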