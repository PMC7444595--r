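# Synthetic benchmark surfaces with analytic ground truth, in voxel units:
# a noisy triangulated plane (normal estimation), spheres with quantization
# noise and with smooth sub-voxel tessellation, a torus (curvature sign, mixed
# Gaussian curvature) and an open cylinder (border effects). Each generator
# returns the mesh together with per-triangle true normals, principal directions
# (where defined) and principal curvatures.

new_benchmark <- function(mesh, truth, shape, params, seed = NULL) {
  structure(list(mesh = mesh, truth = truth, shape = shape, params = params,
                 seed = seed),
            class = "benchmark_surface")
}

#' @export
print.benchmark_surface <- function(x, ...) {
  cat(sprintf("<benchmark_surface> %s (%s), %d triangles\n", x$shape,
              paste(names(x$params), unlist(x$params), sep = "=",
                    collapse = ", "),
              nrow(x$mesh$faces)))
  invisible(x)
}

# run code with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Noisy plane benchmark
#'
#' A regularly triangulated square plane (grid spacing 1 voxel) whose vertices
#' are displaced along their normals by Gaussian noise with standard deviation
#' `noise_fraction` times the average triangle edge length. True normals are the
#' flat plane normal (+z); true curvatures are zero.
#'
#' @param half_size half the plane side length in voxels (default 36, giving
#'   more than 10^4 triangles).
#' @param noise_fraction noise scale as a fraction of the average edge, `>= 0`.
#' @param seed integer seed for the vertex displacements.
#' @return a `benchmark_surface`.
#' @export
make_noisy_plane <- function(half_size = 36, noise_fraction = 0.1, seed = 1L) {
  stopifnot(noise_fraction >= 0)
  g <- seq(-half_size, half_size)
  n <- length(g)
  verts <- cbind(rep(g, times = n), rep(g, each = n), 0)
  id <- function(i, j) (j - 1L) * n + i
  i <- rep(1:(n - 1), times = n - 1)
  j <- rep(1:(n - 1), each = n - 1)
  f1 <- cbind(id(i, j), id(i + 1, j), id(i + 1, j + 1))
  f2 <- cbind(id(i, j), id(i + 1, j + 1), id(i, j + 1))
  faces <- rbind(f1, f2)

  flat <- triangle_mesh(verts, faces)
  avg_edge <- mesh_mean_edge(flat)
  if (noise_fraction > 0) {
    dz <- with_seed(seed, stats::rnorm(n * n, sd = noise_fraction * avg_edge))
    verts[, 3] <- verts[, 3] + dz # vertex normals of the flat plane are +z
  }
  mesh <- triangle_mesh(verts, faces)
  # orient normals consistently toward +z (the side the flat normals point to)
  flip <- mesh$normals[, 3] < 0
  if (any(flip)) {
    mesh$faces[flip, 2:3] <- mesh$faces[flip, 3:2]
    mesh <- triangle_mesh(mesh$vertices, mesh$faces)
  }
  m <- nrow(mesh$faces)
  truth <- tibble::tibble(
    n_x = 0, n_y = 0, n_z = 1,
    kappa_1 = rep(0, m), kappa_2 = rep(0, m)
  )
  new_benchmark(mesh, truth, "plane",
                list(half_size = half_size, noise_fraction = noise_fraction),
                seed = seed)
}

# radial sphere truth at given centroids
sphere_truth <- function(centroids, center, r) {
  d <- centroids - matrix(center, nrow(centroids), 3, byrow = TRUE)
  n <- -unit_rows(d) # inward
  tibble::tibble(n_x = n[, 1], n_y = n[, 2], n_z = n[, 3],
                 kappa_1 = 1 / r, kappa_2 = 1 / r)
}

#' Quantization-noise sphere benchmark
#'
#' A binary voxel ball of radius `r` in a `box`^3 volume, isosurfaced *without*
#' smoothing so that the step-like quantization noise of binary segmentations is
#' retained. True curvatures are `1/r`; true normals point radially inward.
#'
#' @param r sphere radius in voxels.
#' @param box volume side length in voxels (must accommodate the ball).
#' @return a `benchmark_surface`.
#' @export
make_voxel_sphere <- function(r = 10, box = 25) {
  if (2 * r + 2 >= box) stop("sphere radius too large for the volume box")
  center <- rep((box - 1) / 2, 3)
  vol <- ball_mask(box, center, r)
  mesh <- isosurface(vol, level = 0.5)
  new_benchmark(mesh, sphere_truth(mesh$centroids, center, r), "voxel_sphere",
                list(r = r, box = box))
}

#' Smooth sphere benchmark
#'
#' A binary voxel ball smoothed with a 3-D Gaussian (`gauss_sigma`), then
#' isosurfaced, giving a smooth surface with a non-uniform triangle
#' tessellation. Smoothing a ball moves the half-maximum level set inward
#' (curvature shrinkage), so the iso level is chosen as the radially averaged
#' smoothed-field value at distance `r` from the center, which places the
#' extracted surface at the nominal radius and keeps the analytic truth `1/r`
#' valid.
#'
#' @param r sphere radius in voxels.
#' @param gauss_sigma Gaussian sigma in voxels.
#' @param box volume side length in voxels; default leaves a 3-sigma margin.
#' @return a `benchmark_surface`.
#' @export
make_smooth_sphere <- function(r = 10, gauss_sigma = 3.3,
                               box = 2 * (r + ceiling(3 * gauss_sigma)) + 5) {
  center <- rep((box - 1) / 2, 3)
  vol <- ball_mask(box, center, r)
  field <- gaussian_smooth_volume(vol, gauss_sigma)
  level <- radial_field_value(field, center, r)
  mesh <- isosurface(field, level = level)
  new_benchmark(mesh, sphere_truth(mesh$centroids, center, r), "smooth_sphere",
                list(r = r, gauss_sigma = gauss_sigma, box = box))
}

ball_mask <- function(box, center, r) {
  ax <- seq_len(box) - 1
  dx2 <- (ax - center[1])^2
  dy2 <- (ax - center[2])^2
  dz2 <- (ax - center[3])^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  array(as.numeric(d2 <= r^2), dim = c(box, box, box))
}

# mean field value over voxels in a thin shell at distance r from the center
radial_field_value <- function(field, center, r, halfwidth = 0.5) {
  box <- dim(field)
  ax <- seq_len(box[1]) - 1
  d2 <- outer(outer((ax - center[1])^2, (seq_len(box[2]) - 1 - center[2])^2,
                    "+"),
              (seq_len(box[3]) - 1 - center[3])^2, "+")
  d <- sqrt(d2)
  sel <- abs(d - r) <= halfwidth
  # linear fit of field vs distance inside the shell, evaluated at r
  fit <- stats::lm.fit(cbind(1, d[sel] - r), field[sel])
  unname(fit$coefficients[1])
}

#' Torus benchmark
#'
#' Parametric torus mesh (ring radius `rr`, cross-section radius `csr`) with
#' inward normals. True principal curvatures: `kappa_1 = 1/csr` along the tube
#' cross-section and `kappa_2 = cos(psi) / (rr + csr cos(psi))` along the ring,
#' where `psi` is the tube angle (0 at the outer equator); the inner rim
#' (`psi = pi`) has negative `kappa_2`.
#'
#' @param rr ring radius in voxels.
#' @param csr cross-section radius in voxels.
#' @param n_ring,n_tube grid resolution along the ring and the tube.
#' @return a `benchmark_surface`.
#' @export
make_torus <- function(rr = 25, csr = 10, n_ring = 120, n_tube = 48) {
  th <- 2 * pi * (seq_len(n_ring) - 1) / n_ring
  ps <- 2 * pi * (seq_len(n_tube) - 1) / n_tube
  TH <- rep(th, times = n_tube)
  PS <- rep(ps, each = n_ring)
  verts <- cbind((rr + csr * cos(PS)) * cos(TH),
                 (rr + csr * cos(PS)) * sin(TH),
                 csr * sin(PS))
  faces <- wrap_grid_faces(n_ring, n_tube, wrap_i = TRUE, wrap_j = TRUE)
  mesh <- torus_oriented_mesh(verts, faces, rr, csr)
  truth <- torus_truth(mesh$centroids, rr, csr)
  new_benchmark(mesh, truth, "torus",
                list(rr = rr, csr = csr, n_ring = n_ring, n_tube = n_tube))
}

# analytic torus truth at arbitrary surface points
torus_truth <- function(pts, rr, csr) {
  rho <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  cpsi <- (rho - rr) / csr
  spsi <- pts[, 3] / csr
  nn <- sqrt(cpsi^2 + spsi^2)
  cpsi <- cpsi / nn; spsi <- spsi / nn
  ux <- pts[, 1] / rho; uy <- pts[, 2] / rho
  outward <- cbind(cpsi * ux, cpsi * uy, spsi)
  n <- -outward
  # t_1: along the tube cross-section; t_2: along the ring
  t1 <- cbind(-spsi * ux, -spsi * uy, cpsi)
  t2 <- cbind(-uy, ux, 0)
  tibble::tibble(
    n_x = n[, 1], n_y = n[, 2], n_z = n[, 3],
    t_1_x = t1[, 1], t_1_y = t1[, 2], t_1_z = t1[, 3],
    t_2_x = t2[, 1], t_2_y = t2[, 2], t_2_z = t2[, 3],
    kappa_1 = 1 / csr,
    kappa_2 = cpsi / (rr + csr * cpsi)
  )
}

torus_oriented_mesh <- function(verts, faces, rr, csr) {
  mesh <- triangle_mesh(verts, faces)
  tr <- torus_truth(mesh$centroids, rr, csr)
  inward <- cbind(tr$n_x, tr$n_y, tr$n_z)
  flip <- rowSums(mesh$normals * inward) < 0
  if (any(flip)) {
    mesh$faces[flip, 2:3] <- mesh$faces[flip, 3:2]
    mesh <- triangle_mesh(mesh$vertices, mesh$faces)
  }
  mesh
}

#' Open cylinder benchmark
#'
#' Parametric open tube (no caps) of radius `r` and height `h` with inward
#' normals. True `kappa_1 = 1/r` (around the circumference), `kappa_2 = 0` with
#' `t_2` along the axis; the border triangles are exactly the two end rings.
#'
#' @param r cylinder radius in voxels.
#' @param h cylinder height in voxels.
#' @param n_circ,n_z grid resolution around and along the axis.
#' @return a `benchmark_surface`.
#' @export
make_cylinder <- function(r = 10, h = 25, n_circ = 52, n_z = 26) {
  th <- 2 * pi * (seq_len(n_circ) - 1) / n_circ
  zz <- h * (seq_len(n_z) - 1) / (n_z - 1)
  TH <- rep(th, times = n_z)
  Z <- rep(zz, each = n_circ)
  verts <- cbind(r * cos(TH), r * sin(TH), Z)
  faces <- wrap_grid_faces(n_circ, n_z, wrap_i = TRUE, wrap_j = FALSE)
  mesh <- triangle_mesh(verts, faces)
  inward <- -cbind(mesh$centroids[, 1], mesh$centroids[, 2], 0)
  inward <- unit_rows(inward)
  flip <- rowSums(mesh$normals * inward) < 0
  if (any(flip)) {
    mesh$faces[flip, 2:3] <- mesh$faces[flip, 3:2]
    mesh <- triangle_mesh(mesh$vertices, mesh$faces)
  }
  cn <- unit_rows(-cbind(mesh$centroids[, 1], mesh$centroids[, 2], 0))
  t1 <- cbind(-cn[, 2], cn[, 1], 0) # tangential, around the circumference
  m <- nrow(mesh$faces)
  truth <- tibble::tibble(
    n_x = cn[, 1], n_y = cn[, 2], n_z = cn[, 3],
    t_1_x = t1[, 1], t_1_y = t1[, 2], t_1_z = t1[, 3],
    t_2_x = 0, t_2_y = 0, t_2_z = 1,
    kappa_1 = 1 / r, kappa_2 = rep(0, m)
  )
  new_benchmark(mesh, truth, "cylinder",
                list(r = r, h = h, n_circ = n_circ, n_z = n_z))
}

# triangulate an n_i x n_j parameter grid, optionally wrapping either axis
wrap_grid_faces <- function(n_i, n_j, wrap_i = FALSE, wrap_j = FALSE) {
  id <- function(i, j) (j - 1L) * n_i + i
  imax <- if (wrap_i) n_i else n_i - 1L
  jmax <- if (wrap_j) n_j else n_j - 1L
  i <- rep(seq_len(imax), times = jmax)
  j <- rep(seq_len(jmax), each = imax)
  ip <- i %% n_i + 1L
  jp <- j %% n_j + 1L
  rbind(
    cbind(id(i, j), id(ip, j), id(ip, jp)),
    cbind(id(i, j), id(ip, jp), id(i, jp))
  )
}
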