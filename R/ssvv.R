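# Surface Sampling Vector Voting: instead of voting from all geodesic neighbors,
# eight surface points at tangent distance radius_hit are sampled by intersecting
# the mesh with lines parallel to the estimated normal, and each sample
# contributes the curvature of the osculating circle through the center that is
# tangent to the sampling direction and passes through the intersection point.

#' SSVV curvature tensor for one triangle
#'
#' An initial tangent at `v` (deterministic: the normalized projection of the
#' global x-axis onto the tangent plane, falling back to the y-axis) of length
#' `rh` defines a point `v_t`; the line through `v_t` parallel to the estimated
#' normal `n_v` is intersected with the mesh and the nearest intersection `c`
#' within distance `2 * rh` of `v_t` (excluding the receiving triangle) is kept.
#' The tangent is rotated seven times by `pi/4` around `n_v`. Each hit yields a
#' signed curvature `kappa_i = 2 h / (rh^2 + h^2)` with `h = n_v . (c - v_t)`
#' (the osculating circle through `v` tangent to the sampling direction; exact on
#' spheres), and the tensor is `B_v = (1/8) sum kappa_i t_i t_i^T` over the found
#' intersections. Fewer than three hits flag the triangle (no tensor), which is
#' what makes the algorithm collapse when `rh` reaches the feature radius.
#'
#' @param mesh a `triangle_mesh`.
#' @param v receiving triangle index.
#' @param n_v estimated unit normal at `v`.
#' @param rh sampling radius `radius_hit` (mesh units).
#' @param cache per-mesh ray-casting precomputation from [ssvv_cache()];
#'   computed on the fly when `NULL` (pass it explicitly in whole-mesh loops).
#' @return a 3x3 symmetric matrix, or `NULL` when fewer than three rays hit.
#' @export
ssvv_tensor <- function(mesh, v, n_v, rh, cache = NULL) {
  if (is.null(cache)) cache <- ssvv_cache(mesh)
  centroid <- mesh$centroids[v, ]

  t0 <- tangent_direction(centroid, n_v, centroid + c(1, 0, 0))
  if (is.null(t0)) t0 <- tangent_direction(centroid, n_v, centroid + c(0, 1, 0))
  u2 <- c(
    n_v[2] * t0[3] - n_v[3] * t0[2],
    n_v[3] * t0[1] - n_v[1] * t0[3],
    n_v[1] * t0[2] - n_v[2] * t0[1]
  )

  # prefilter: a hit lies within 2*rh of v_t, v_t within rh of v
  reach <- 3 * rh + 2 * cache$max_edge
  near <- which(row_norms(mesh$centroids -
                            matrix(centroid, nrow(mesh$centroids), 3,
                                   byrow = TRUE)) <= reach)
  near <- near[near != v]
  if (length(near) == 0L) return(NULL)

  ang <- (0:7) * pi / 4
  hits_t <- matrix(0, 0, 3)
  hits_k <- numeric(0)
  for (a in ang) {
    tang <- cos(a) * t0 + sin(a) * u2
    v_t <- centroid + rh * tang
    s <- ray_mesh_intersect(cache, near, v_t, n_v, max_abs = 2 * rh)
    if (is.na(s)) next
    hits_t <- rbind(hits_t, tang)
    hits_k <- c(hits_k, 2 * s / (rh^2 + s^2))
  }
  if (length(hits_k) < 3L) return(NULL)
  B <- crossprod(hits_t, hits_t * hits_k) / 8
  (B + t(B)) / 2
}

#' Ray-casting precomputation for SSVV
#'
#' Precomputes per-triangle edge vectors and the maximum edge length used by the
#' line-mesh intersection in [ssvv_tensor()].
#'
#' @param mesh a `triangle_mesh`.
#' @return a list with `p1`, `e1`, `e2` (m x 3 matrices) and `max_edge`.
#' @export
ssvv_cache <- function(mesh) {
  p1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  p2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  p3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  list(
    p1 = p1, e1 = p2 - p1, e2 = p3 - p1,
    max_edge = max(row_norms(p2 - p1), row_norms(p3 - p2), row_norms(p1 - p3))
  )
}

# Moeller-Trumbore over a triangle subset for the full line orig + s * dir;
# returns the signed offset s of the nearest hit (min |s|, |s| <= max_abs) or NA
ray_mesh_intersect <- function(cache, subset, orig, dir, max_abs) {
  p1 <- cache$p1[subset, , drop = FALSE]
  e1 <- cache$e1[subset, , drop = FALSE]
  e2 <- cache$e2[subset, , drop = FALSE]
  k <- nrow(p1)
  dmat <- matrix(dir, k, 3, byrow = TRUE)
  h <- row_cross(dmat, e2)
  a <- rowSums(e1 * h)
  ok <- abs(a) > 1e-12
  if (!any(ok)) return(NA_real_)
  f <- ifelse(ok, 1 / a, NA_real_)
  sp <- matrix(orig, k, 3, byrow = TRUE) - p1
  u <- f * rowSums(sp * h)
  q <- row_cross(sp, e1)
  vv <- f * rowSums(dmat * q)
  s <- f * rowSums(e2 * q)
  hit <- ok & u >= 0 & u <= 1 & vv >= 0 & (u + vv) <= 1 & abs(s) <= max_abs
  if (!any(hit, na.rm = TRUE)) return(NA_real_)
  s <- s[which(hit)]
  s[which.min(abs(s))]
}
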