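cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                          a[3] * b[1] - a[1] * b[3],
                          a[1] * b[2] - a[2] * b[1])

test_that("triangle_mesh validates input and computes geometry", {
  expect_error(triangle_mesh(matrix(0, 3, 3), matrix(integer(0), 0, 3)),
               "empty mesh")
  expect_error(triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                             rbind(c(1, 2, 2))), "distinct")
  expect_error(triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                             rbind(c(1, 2, 5))), "out of range")
  m <- triangle_mesh(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0)),
                     rbind(c(1, 2, 3)))
  expect_equal(m$areas, 2)
  expect_equal(m$centroids[1, ], c(2 / 3, 2 / 3, 0))
  expect_equal(sqrt(sum(m$normals[1, ]^2)), 1)
  # supplied normals flip the winding to agree
  m2 <- triangle_mesh(m$vertices, m$faces, normals = matrix(c(0, 0, -1), 1))
  expect_equal(m2$normals[1, ], c(0, 0, -1))
  cr <- cross(m2$vertices[m2$faces[1, 2], ] - m2$vertices[m2$faces[1, 1], ],
              m2$vertices[m2$faces[1, 3], ] - m2$vertices[m2$faces[1, 1], ])
  expect_gt(sum(cr * m2$normals[1, ]), 0)
})

test_that("surface graph classifies strong and weak edges", {
  g <- build_surface_graph(strip_two())
  expect_equal(g$n, 2)
  expect_equal(sum(igraph::E(g$graph)$type == "strong"), 1)
  expect_equal(sum(igraph::E(g$graph)$type == "weak"), 0)

  g2 <- build_surface_graph(bowtie_two())
  expect_equal(sum(igraph::E(g2$graph)$type == "strong"), 0)
  expect_equal(sum(igraph::E(g2$graph)$type == "weak"), 1)

  # closed tetrahedron: all 6 face pairs share an edge (enumerated oracle)
  tet <- tetrahedron_mesh()
  shared <- combn(4, 2, function(p)
    length(intersect(tet$faces[p[1], ], tet$faces[p[2], ])))
  expect_true(all(shared == 2))
  g3 <- build_surface_graph(tet)
  expect_equal(sum(igraph::E(g3$graph)$type == "strong"), 6)
  expect_equal(sum(igraph::E(g3$graph)$type == "weak"), 0)
  expect_length(detect_borders(g3), 0)

  # edge lengths are centroid distances
  el <- export_edge_list(g)
  expect_equal(el$length,
               sqrt(sum((g$centroids[1, ] - g$centroids[2, ])^2)))
})

test_that("geodesic neighborhoods match hand counts and a brute-force oracle", {
  g <- build_surface_graph(linear_strip(8))
  expect_equal(nrow(geodesic_neighborhood(g, 5, 0)), 0)

  # along the strip interior, centroids alternate in two rows; pick a mid
  # triangle and check against Floyd-Warshall everywhere
  D <- floyd_warshall(g)
  for (v in c(1, 7, 12)) {
    for (gm in c(1.5, 3, 100)) {
      nb <- geodesic_neighborhood(g, v, gm)
      oracle <- which(D[v, ] <= gm & seq_len(g$n) != v)
      expect_setequal(nb$triangle, oracle)
      expect_equal(nb$geodesic, D[v, nb$triangle], tolerance = 1e-12)
    }
  }

  # geodesic >= Euclidean straight-line distance
  nb <- geodesic_neighborhood(g, 1, 100)
  eu <- sqrt(rowSums((g$centroids[nb$triangle, , drop = FALSE] -
                        matrix(g$centroids[1, ], nrow(nb), 3,
                               byrow = TRUE))^2))
  expect_true(all(nb$geodesic >= eu - 1e-12))
})

test_that("geodesics on a closed mesh equal the oracle and weak edges only shorten paths", {
  mesh <- uv_sphere(3, n_th = 10, n_ph = 5) # 100 triangles
  g <- build_surface_graph(mesh)
  D <- floyd_warshall(g)
  Dg <- igraph::distances(g$graph, algorithm = "dijkstra")
  expect_equal(unname(Dg), D, tolerance = 1e-10)

  strong_only <- igraph::subgraph_from_edges(
    g$graph, igraph::E(g$graph)[igraph::E(g$graph)$type == "strong"],
    delete.vertices = FALSE
  )
  Ds <- igraph::distances(strong_only, algorithm = "dijkstra")
  expect_true(all(Dg <= Ds + 1e-12))
})

test_that("border detection and filtering behave on open and closed meshes", {
  single <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                          rbind(c(1, 2, 3)))
  expect_equal(detect_borders(build_surface_graph(single)), 1)

  cyl <- make_cylinder(5, 12, n_circ = 20, n_z = 10)
  g <- build_surface_graph(cyl$mesh)
  expect_setequal(detect_borders(g), boundary_triangles(cyl$mesh))

  # reindexing invariance
  perm <- rev(seq_len(nrow(cyl$mesh$faces)))
  mesh_p <- triangle_mesh(cyl$mesh$vertices, cyl$mesh$faces[perm, ],
                          normals = cyl$mesh$normals[perm, ])
  bp <- detect_borders(build_surface_graph(mesh_p))
  expect_setequal(perm[bp], detect_borders(g))

  # closed surface: no borders, filtering is a no-op
  tet <- tetrahedron_mesh()
  gt <- build_surface_graph(tet)
  expect_identical(filter_borders(tet, gt, 10)$faces, tet$faces)
  expect_identical(filter_borders(cyl$mesh, g, 0)$faces, cyl$mesh$faces)

  # exclusion removes everything within the geodesic band (independent check:
  # multi-source Dijkstra from the boundary triangles on the original graph)
  excl <- 3
  kept <- filter_borders(cyl$mesh, g, excl)
  D <- igraph::distances(g$graph, v = detect_borders(g),
                         algorithm = "dijkstra")
  d_border <- apply(D, 2, min)
  ckey <- function(m) paste(round(m[, 1], 6), round(m[, 2], 6),
                            round(m[, 3], 6))
  expect_setequal(ckey(kept$centroids),
                  ckey(cyl$mesh$centroids[d_border > excl, , drop = FALSE]))
  expect_error(filter_borders(cyl$mesh, g, 1e6), "fully removed")
})
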