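# Small fixtures built in code, plus independent oracles used across tests.

# two triangles sharing a full edge
strip_two <- function() {
  triangle_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1, 0), c(1.5, 1, 0)),
    rbind(c(1, 2, 3), c(2, 4, 3))
  )
}

# two triangles sharing exactly one vertex
bowtie_two <- function() {
  triangle_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1, 0),
          c(0.5, -1, 0), c(1.5, -1, 0)),
    rbind(c(1, 2, 3), c(2, 4, 5))
  )
}

tetrahedron_mesh <- function() {
  triangle_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1, 0), c(0.5, 0.5, 1)),
    rbind(c(1, 2, 3), c(1, 2, 4), c(2, 3, 4), c(1, 3, 4))
  )
}

# linear strip of 2*k triangles with (k+1) x 2 grid vertices, spacing s
linear_strip <- function(k = 8, s = 1) {
  xs <- seq(0, k) * s
  verts <- rbind(cbind(xs, 0, 0), cbind(xs, s, 0))
  n <- k + 1
  faces <- do.call(rbind, lapply(seq_len(k), function(i)
    rbind(c(i, i + 1, i + n), c(i + 1, i + 1 + n, i + n))))
  triangle_mesh(verts, faces)
}

# parametric UV sphere with exact inward normals (analytic benchmark surface)
uv_sphere <- function(r = 10, n_th = 48, n_ph = 24, center = c(0, 0, 0)) {
  th <- 2 * pi * (seq_len(n_th) - 1) / n_th
  ph <- pi * seq_len(n_ph - 1) / n_ph # exclude poles
  TH <- rep(th, times = length(ph))
  PH <- rep(ph, each = n_th)
  ring <- cbind(r * sin(PH) * cos(TH), r * sin(PH) * sin(TH), r * cos(PH))
  verts <- rbind(c(0, 0, r), ring, c(0, 0, -r))
  id <- function(i, j) 1L + (j - 1L) * n_th + i # ring vertex (i in 1..n_th)
  faces <- list()
  for (i in seq_len(n_th)) {
    ip <- i %% n_th + 1L
    faces[[length(faces) + 1L]] <- c(1L, id(i, 1L), id(ip, 1L))
    faces[[length(faces) + 1L]] <- c(nrow(verts), id(ip, length(ph)),
                                     id(i, length(ph)))
  }
  for (j in seq_len(length(ph) - 1L)) {
    for (i in seq_len(n_th)) {
      ip <- i %% n_th + 1L
      faces[[length(faces) + 1L]] <- c(id(i, j), id(ip, j), id(ip, j + 1L))
      faces[[length(faces) + 1L]] <- c(id(i, j), id(ip, j + 1L), id(i, j + 1L))
    }
  }
  verts <- sweep(verts, 2, -center, "-")
  mesh <- triangle_mesh(verts, do.call(rbind, faces))
  inward <- -(mesh$centroids - matrix(center, nrow(mesh$centroids), 3,
                                      byrow = TRUE))
  flip <- rowSums(mesh$normals * inward) < 0
  if (any(flip)) {
    mesh$faces[flip, 2:3] <- mesh$faces[flip, 3:2]
    mesh <- triangle_mesh(mesh$vertices, mesh$faces)
  }
  mesh
}

# independent all-pairs shortest-path oracle (Floyd-Warshall)
floyd_warshall <- function(graph) {
  n <- graph$n
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  el <- igraph::as_edgelist(graph$graph)
  w <- igraph::E(graph$graph)$weight
  for (k in seq_len(nrow(el))) {
    i <- el[k, 1]; j <- el[k, 2]
    D[i, j] <- min(D[i, j], w[k])
    D[j, i] <- D[i, j]
  }
  for (k in seq_len(n)) {
    Dk <- outer(D[, k], D[k, ], "+")
    D <- pmin(D, Dk)
  }
  D
}

# boundary triangles straight from the mesh: faces owning an edge used once
boundary_triangles <- function(mesh) {
  f <- mesh$faces
  ed <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  once <- names(table(key))[table(key) == 1]
  owner <- rep(seq_len(nrow(f)), 3)
  sort(unique(owner[key %in% once]))
}

# finite-difference principal curvatures of a parametric surface at (u, v):
# first/second fundamental forms by central differences
fd_principal_curvatures <- function(fun, u, v, h = 1e-4) {
  xu <- (fun(u + h, v) - fun(u - h, v)) / (2 * h)
  xv <- (fun(u, v + h) - fun(u, v - h)) / (2 * h)
  xuu <- (fun(u + h, v) - 2 * fun(u, v) + fun(u - h, v)) / h^2
  xvv <- (fun(u, v + h) - 2 * fun(u, v) + fun(u, v - h)) / h^2
  xuv <- (fun(u + h, v + h) - fun(u + h, v - h) -
            fun(u - h, v + h) + fun(u - h, v - h)) / (4 * h^2)
  nrm <- c(xu[2] * xv[3] - xu[3] * xv[2],
           xu[3] * xv[1] - xu[1] * xv[3],
           xu[1] * xv[2] - xu[2] * xv[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  E <- sum(xu * xu); Fq <- sum(xu * xv); G <- sum(xv * xv)
  L <- sum(xuu * nrm); M <- sum(xuv * nrm); N <- sum(xvv * nrm)
  # shape operator eigenvalues
  S <- solve(matrix(c(E, Fq, Fq, G), 2), matrix(c(L, M, M, N), 2))
  ev <- eigen(S)$values
  sort(Re(ev), decreasing = TRUE)
}
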