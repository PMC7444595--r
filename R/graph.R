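# Surface graph: one vertex per triangle at its centroid; triangles sharing an
# edge (two mesh vertices) are linked by strong edges, triangles sharing a single
# mesh vertex by weak edges. Shortest paths over both edge types approximate
# geodesic distances along the surface.

#' Build the surface graph of a triangle mesh
#'
#' Maps a triangle mesh into a spatially embedded graph: graph vertices are
#' triangle centroids; pairs of triangles sharing exactly two mesh vertices are
#' connected by *strong* edges and pairs sharing exactly one mesh vertex by
#' *weak* edges. Edge lengths are Euclidean distances between the two centroids.
#' Border triangles are those with fewer than three strong edges.
#'
#' @param mesh a `triangle_mesh`.
#' @return an object of class `surface_graph`: a list with `graph` (an
#'   [igraph::igraph] with edge attributes `weight` (length) and `type`
#'   ("strong"/"weak")), `centroids`, `border` (logical per triangle) and `n`.
#' @export
build_surface_graph <- function(mesh) {
  if (!inherits(mesh, "triangle_mesh")) stop("mesh must be a triangle_mesh")
  m <- nrow(mesh$faces)
  if (m == 0L) stop("empty mesh")

  # pairs of triangles sharing >=1 vertex, with multiplicity = shared vertex count
  f <- mesh$faces
  tri_of_vertex <- split(rep(seq_len(m), 3L), as.vector(f))
  pair_list <- lapply(tri_of_vertex, function(tr) {
    if (length(tr) < 2L) return(NULL)
    tr <- sort(tr)
    cbind(rep(tr, times = rev(seq_along(tr)) - 1L),
          unlist(lapply(seq_along(tr)[-1L], function(i) tr[i:length(tr)]), use.names = FALSE))
  })
  # the above builds, for each vertex, all unordered triangle pairs incident to it
  pairs <- do.call(rbind, pair_list)
  if (is.null(pairs)) pairs <- matrix(integer(0), ncol = 2L)
  key <- (pairs[, 1] - 1) * m + pairs[, 2]
  shared <- table(key)
  ukey <- as.numeric(names(shared))
  i <- floor((ukey - 1) / m) + 1
  j <- ukey - (i - 1) * m
  nshared <- as.integer(shared)
  type <- ifelse(nshared >= 2L, "strong", "weak")

  lens <- row_norms(mesh$centroids[i, , drop = FALSE] -
                      mesh$centroids[j, , drop = FALSE])
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  if (length(i) > 0) {
    g <- igraph::add_edges(g, rbind(i, j))
    igraph::E(g)$weight <- lens
    igraph::E(g)$type <- type
  }

  strong_deg <- rep(0L, m)
  si <- type == "strong"
  if (any(si)) {
    tb <- table(c(i[si], j[si]))
    strong_deg[as.integer(names(tb))] <- as.integer(tb)
  }

  structure(
    list(graph = g, centroids = mesh$centroids, border = strong_deg < 3L,
         n = m,
         # 0-based edge arrays for the compiled voting kernels
         edges = list(i = as.integer(i - 1L), j = as.integer(j - 1L),
                      w = as.numeric(lens))),
    class = "surface_graph"
  )
}

#' @export
print.surface_graph <- function(x, ...) {
  et <- igraph::E(x$graph)$type
  cat(sprintf("<surface_graph> %d vertices, %d strong + %d weak edges, %d border\n",
              x$n, sum(et == "strong"), sum(et == "weak"), sum(x$border)))
  invisible(x)
}

#' Geodesic neighborhood of a triangle
#'
#' All graph vertices (triangles) whose shortest-path distance from `v` along
#' strong and weak edges is at most `g_max`, with their geodesic distances.
#' The query vertex itself is excluded.
#'
#' @param graph a `surface_graph`.
#' @param v triangle index (graph vertex).
#' @param g_max maximum geodesic distance (same units as the mesh).
#' @return a tibble with columns `triangle` and `geodesic`.
#' @export
geodesic_neighborhood <- function(graph, v, g_max) {
  stopifnot(inherits(graph, "surface_graph"), length(v) == 1L,
            v >= 1, v <= graph$n, g_max >= 0)
  d <- as.vector(igraph::distances(graph$graph, v = v, algorithm = "dijkstra"))
  sel <- which(d <= g_max & seq_len(graph$n) != v & is.finite(d))
  tibble::tibble(triangle = sel, geodesic = d[sel])
}

# distance rows for a chunk of source vertices; returns chunk x n matrix
geodesic_rows <- function(graph, v) {
  igraph::distances(graph$graph, v = v, algorithm = "dijkstra")
}

#' Detect border triangles
#'
#' Border triangles are exactly those with fewer than three strong edges in the
#' surface graph (open mesh boundaries, holes, isolated triangles).
#'
#' @param graph a `surface_graph`.
#' @return integer vector of border triangle indices.
#' @export
detect_borders <- function(graph) {
  stopifnot(inherits(graph, "surface_graph"))
  which(graph$border)
}

#' Geodesic distance of every triangle to the nearest border triangle
#'
#' Multi-source Dijkstra from all border vertices. Border triangles themselves
#' have distance 0; on a closed surface all distances are `Inf`.
#'
#' @param graph a `surface_graph`.
#' @return numeric vector of length `graph$n`.
#' @export
border_distances <- function(graph) {
  borders <- detect_borders(graph)
  if (length(borders) == 0L) return(rep(Inf, graph$n))
  # auxiliary source tied to every border vertex with zero-length edges
  g2 <- igraph::add_vertices(graph$graph, 1L)
  aux <- graph$n + 1L
  g2 <- igraph::add_edges(g2, rbind(rep(aux, length(borders)), borders),
                          attr = list(weight = rep(0, length(borders))))
  d <- as.vector(igraph::distances(g2, v = aux, algorithm = "dijkstra"))
  d[seq_len(graph$n)]
}

#' Remove triangles near open borders
#'
#' Drops every triangle whose centroid lies within geodesic distance `exclusion`
#' of a border triangle (tensor-voting estimates degrade there). With
#' `exclusion = 0` or on a closed surface the mesh is returned unchanged.
#'
#' @param mesh a `triangle_mesh`.
#' @param graph its `surface_graph`.
#' @param exclusion geodesic distance (same units as the mesh), `>= 0`.
#' @return the filtered `triangle_mesh`.
#' @export
filter_borders <- function(mesh, graph, exclusion) {
  stopifnot(exclusion >= 0)
  if (exclusion == 0) return(mesh)
  d <- border_distances(graph)
  keep <- d > exclusion
  if (!any(keep)) stop("surface fully removed")
  subset_triangles(mesh, keep)
}

#' Export the surface graph as a plain edge list
#'
#' Writes (or returns) a table with one row per edge: `source`, `target`,
#' `type` ("strong"/"weak") and Euclidean `length`. Intended for debugging.
#'
#' @param graph a `surface_graph`.
#' @param path optional file path; if given, written as tab-separated text.
#' @return the edge-list tibble, invisibly when `path` is given.
#' @export
export_edge_list <- function(graph, path = NULL) {
  el <- igraph::as_edgelist(graph$graph)
  out <- tibble::tibble(
    source = as.integer(el[, 1]), target = as.integer(el[, 2]),
    type = igraph::E(graph$graph)$type,
    length = igraph::E(graph$graph)$weight
  )
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}
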