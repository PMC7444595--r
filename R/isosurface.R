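# Isosurface extraction by the Marching Cubes algorithm. The 256-entry case
# table is generated at load time from first principles instead of being typed
# in: for every corner sign pattern, the cut edges of each cube face are paired
# (on ambiguous faces the rule "inside corners are separated" is used, which is
# symmetric across neighboring cubes and therefore watertight), the resulting
# closed polygons are traced and fan-triangulated. Vertices are linearly
# interpolated along cube edges, giving sub-voxel precision on smooth volumes.
# Triangles are oriented so normals point toward values above the level (the
# inside of a filled mask), matching the convention that normals point inwards
# on a convex closed surface.

# corner coordinates of the unit cube (VTK/MC ordering), 1-based ids
.cube_corners <- cbind(
  x = c(0, 1, 1, 0, 0, 1, 1, 0),
  y = c(0, 0, 1, 1, 0, 0, 1, 1),
  z = c(0, 0, 0, 0, 1, 1, 1, 1)
)

# the 12 cube edges as corner-id pairs
.cube_edges <- rbind(
  c(1, 2), c(2, 3), c(3, 4), c(4, 1), # bottom (z = 0)
  c(5, 6), c(6, 7), c(7, 8), c(8, 5), # top (z = 1)
  c(1, 5), c(2, 6), c(3, 7), c(4, 8) # verticals
)

# the 6 cube faces as corner-id quadruples (cyclic order)
.cube_faces <- rbind(
  c(1, 2, 3, 4),
  c(5, 6, 7, 8),
  c(1, 2, 6, 5),
  c(4, 3, 7, 8),
  c(1, 4, 8, 5),
  c(2, 3, 7, 6)
)

# edge id joining two corners (0 if not a cube edge)
.edge_lookup <- local({
  m <- matrix(0L, 8, 8)
  for (e in seq_len(nrow(.cube_edges))) {
    m[.cube_edges[e, 1], .cube_edges[e, 2]] <- e
    m[.cube_edges[e, 2], .cube_edges[e, 1]] <- e
  }
  m
})

# Build the triangulation of one corner-sign case: returns NULL or a list of
# polygons, each an integer vector of cube-edge ids in cyclic order.
mc_case_polygons <- function(inside) {
  cut <- which(xor(inside[.cube_edges[, 1]], inside[.cube_edges[, 2]]))
  if (length(cut) == 0L) return(NULL)
  # partner of each cut edge within each face
  links <- vector("list", 12L)
  for (f in seq_len(nrow(.cube_faces))) {
    corners <- .cube_faces[f, ]
    fe <- vapply(1:4, function(k)
      .edge_lookup[corners[k], corners[k %% 4 + 1]], integer(1))
    fcut <- fe[fe %in% cut]
    if (length(fcut) == 2L) {
      links[[fcut[1]]] <- c(links[[fcut[1]]], fcut[2])
      links[[fcut[2]]] <- c(links[[fcut[2]]], fcut[1])
    } else if (length(fcut) == 4L) {
      # ambiguous face: connect the two cut edges incident to each inside
      # corner, so that inside corners are separated (watertight rule)
      for (corner in corners[inside[corners]]) {
        inc <- fcut[.cube_edges[fcut, 1] == corner |
                      .cube_edges[fcut, 2] == corner]
        links[[inc[1]]] <- c(links[[inc[1]]], inc[2])
        links[[inc[2]]] <- c(links[[inc[2]]], inc[1])
      }
    }
  }
  # trace disjoint cycles; with each cycle keep the above-level ("inside")
  # endpoint corners of its cut edges, used as the orientation reference
  polys <- list()
  remaining <- cut
  while (length(remaining) > 0L) {
    start <- remaining[1]
    cycle <- start
    prev <- 0L
    cur <- start
    repeat {
      nxt <- setdiff(links[[cur]], prev)[1]
      if (nxt == start) break
      cycle <- c(cycle, nxt)
      prev <- cur
      cur <- nxt
    }
    ends <- .cube_edges[cycle, , drop = FALSE]
    inner <- ifelse(inside[ends[, 1]], ends[, 1], ends[, 2])
    polys[[length(polys) + 1L]] <- list(edges = cycle,
                                        inner = unique(inner))
    remaining <- setdiff(remaining, cycle)
  }
  polys
}

# case table: for each of the 256 corner patterns, the list of traced polygons
# (cube-edge ids in cyclic order); triangulated as fans at extraction time
.mc_table <- local({
  tab <- vector("list", 256L)
  for (code in 0:255) {
    inside <- as.logical(bitwAnd(code, 2^(0:7)))
    polys <- mc_case_polygons(inside)
    if (!is.null(polys)) tab[[code + 1L]] <- polys
  }
  tab
})

#' Extract an isosurface from a 3-D volume
#'
#' Marching-cubes triangulation of the level set `volume = level` (case table
#' generated at load time; ambiguous faces resolved by separating above-level
#' corners, which keeps the mesh watertight). Voxel centers sit at 0-based
#' integer coordinates; linear interpolation along cube edges gives sub-voxel
#' precision on smooth volumes. The returned mesh is oriented with normals
#' pointing toward values above `level` (the inside of a filled mask).
#'
#' @param volume 3-D numeric array.
#' @param level iso level; for binary masks the natural half-maximum is 0.5.
#' @return a `triangle_mesh` (voxel units).
#' @export
isosurface <- function(volume, level = 0.5) {
  d <- dim(volume)
  if (length(d) != 3L) stop("volume must be a 3-D array")
  if (min(volume) >= level || max(volume) < level)
    stop(sprintf("isosurface empty at level %g (volume range [%g, %g])",
                 level, min(volume), max(volume)))

  nc <- d - 1L
  ci <- arrayInd(seq_len(prod(nc)), nc) # 1-based cell origin voxel
  corner_vals <- matrix(0, nrow(ci), 8)
  for (cc in 1:8) {
    off <- .cube_corners[cc, ]
    corner_vals[, cc] <- volume[cbind(ci[, 1] + off[1], ci[, 2] + off[2],
                                      ci[, 3] + off[3])]
  }
  above <- corner_vals > level
  code <- as.integer(above %*% 2^(0:7))
  active <- which(code > 0L & code < 255L)
  if (length(active) == 0L) stop(sprintf("isosurface empty at level %g", level))
  ci <- ci[active, , drop = FALSE]
  corner_vals <- corner_vals[active, , drop = FALSE]
  code <- code[active]
  origin <- ci - 1L # 0-based voxel coordinate of cube corner 1

  # interpolated point on a cube edge, vectorized over cells
  edge_point <- function(e, rows) {
    a <- .cube_edges[e, 1]; b <- .cube_edges[e, 2]
    va <- corner_vals[rows, a]; vb <- corner_vals[rows, b]
    tt <- (level - va) / (vb - va)
    pa <- origin[rows, , drop = FALSE] +
      matrix(.cube_corners[a, ], length(rows), 3, byrow = TRUE)
    pb <- origin[rows, , drop = FALSE] +
      matrix(.cube_corners[b, ], length(rows), 3, byrow = TRUE)
    pa + tt * (pb - pa)
  }

  tri_list <- list()
  for (cd in sort(unique(code))) {
    polys <- .mc_table[[cd + 1L]]
    if (is.null(polys)) next
    rows <- which(code == cd)
    for (poly in polys) {
      p <- poly$edges
      # orientation reference: mean position of this polygon's own
      # above-level corners
      ref <- matrix(0, length(rows), 3)
      for (cc in poly$inner) {
        ref <- ref + origin[rows, , drop = FALSE] +
          matrix(.cube_corners[cc, ], length(rows), 3, byrow = TRUE)
      }
      ref <- ref / length(poly$inner)
      pts <- lapply(p, edge_point, rows = rows)
      # Newell normal of the polygon, oriented toward the above-level side;
      # deciding the flip once per polygon keeps the whole fan consistent
      nn <- matrix(0, length(rows), 3)
      ctr <- matrix(0, length(rows), 3)
      np <- length(pts)
      for (k in seq_len(np)) {
        a <- pts[[k]]; b <- pts[[k %% np + 1L]]
        nn <- nn + row_cross(a, b)
        ctr <- ctr + a
      }
      ctr <- ctr / np
      flip <- rowSums(nn * (ref - ctr)) < 0
      for (k in 2:(np - 1L)) {
        q2 <- pts[[k]]; q3 <- pts[[k + 1L]]
        t2 <- q2
        q2[flip, ] <- q3[flip, , drop = FALSE]
        q3[flip, ] <- t2[flip, , drop = FALSE]
        tri_list[[length(tri_list) + 1L]] <- cbind(pts[[1]], q2, q3)
      }
    }
  }

  V <- do.call(rbind, tri_list)
  p1 <- V[, 1:3, drop = FALSE]
  p2 <- V[, 4:6, drop = FALSE]
  p3 <- V[, 7:9, drop = FALSE]
  # drop degenerate slivers (the level hitting a corner value exactly)
  nrm <- row_cross(p2 - p1, p3 - p1)
  keep <- row_norms(nrm) / 2 > DEGENERATE_AREA
  p1 <- p1[keep, , drop = FALSE]; p2 <- p2[keep, , drop = FALSE]
  p3 <- p3[keep, , drop = FALSE]
  if (nrow(p1) == 0L) stop(sprintf("isosurface empty at level %g", level))

  # merge duplicated vertices (identical interpolated coordinates across cubes
  # up to float noise; round to a fine grid for the key)
  allp <- rbind(p1, p2, p3)
  key <- paste(round(allp[, 1], 7), round(allp[, 2], 7), round(allp[, 3], 7),
               sep = "_")
  uid <- match(key, unique(key))
  verts <- allp[!duplicated(uid), , drop = FALSE]
  m <- nrow(p1)
  faces <- cbind(uid[1:m], uid[(m + 1):(2 * m)], uid[(2 * m + 1):(3 * m)])
  ok <- faces[, 1] != faces[, 2] & faces[, 1] != faces[, 3] &
    faces[, 2] != faces[, 3]
  triangle_mesh(verts, faces[ok, , drop = FALSE])
}
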