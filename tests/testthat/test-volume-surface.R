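test_that("segmentation volumes validate and coerce input", {
  expect_error(segmentation_volume(matrix(0, 3, 3)), "3-D")
  expect_error(segmentation_volume(array(0, c(2, 2, 2)), voxel_size = 0),
               "positive")
  expect_warning(v <- segmentation_volume(array(c(0, 2, 5, 0), c(2, 2, 1))),
                 "coerced")
  expect_setequal(unique(as.vector(v$data)), c(0, 1))
})

test_that("gaussian smoothing matches a brute-force convolution oracle", {
  set.seed(11)
  a <- array(runif(6 * 5 * 4), c(6, 5, 4))
  sigma <- 0.8
  out <- gaussian_smooth_volume(a, sigma)
  r <- ceiling(4 * sigma)
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  brute <- array(0, dim(a))
  for (i in 1:6) for (j in 1:5) for (l in 1:4) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) for (dl in -r:r) {
      ii <- i + di; jj <- j + dj; ll <- l + dl
      if (ii >= 1 && ii <= 6 && jj >= 1 && jj <= 5 && ll >= 1 && ll <= 4)
        acc <- acc + k[di + r + 1] * k[dj + r + 1] * k[dl + r + 1] * a[ii, jj, ll]
    }
    brute[i, j, l] <- acc
  }
  expect_equal(out, brute, tolerance = 1e-12)
  expect_identical(gaussian_smooth_volume(a, 0), a)
})

test_that("distance_to_mask matches brute force", {
  set.seed(3)
  mask <- array(0, c(7, 6, 5))
  mask[sample(length(mask), 12)] <- 1
  pts <- cbind(runif(20, 0, 6), runif(20, 0, 5), runif(20, 0, 4))
  d <- distance_to_mask(pts, mask)
  vox <- which(mask > 0, arr.ind = TRUE) - 1
  brute <- apply(pts, 1, function(p)
    sqrt(min(colSums((t(vox) - p)^2))))
  expect_equal(d, brute, tolerance = 1e-12)
  expect_true(all(is.infinite(distance_to_mask(pts, array(0, c(3, 3, 3))))))
})

test_that("isosurface extracts watertight oriented meshes", {
  # filled axis-aligned cube: closed box-like mesh with inward normals
  vol <- array(0, c(14, 14, 14))
  vol[3:12, 3:12, 3:12] <- 1
  mesh <- isosurface(vol, level = 0.5)
  ctr <- colMeans(mesh$vertices)
  outward <- mesh$centroids - matrix(ctr, nrow(mesh$centroids), 3, byrow = TRUE)
  expect_true(all(rowSums(mesh$normals * outward) < 0))
  g <- build_surface_graph(mesh)
  expect_length(detect_borders(g), 0)

  # smoothed ball: sub-voxel vertices within r +- 1 voxel
  box <- 27
  ax <- seq_len(box) - 1
  c0 <- (box - 1) / 2
  d2 <- outer(outer((ax - c0)^2, (ax - c0)^2, "+"), (ax - c0)^2, "+")
  ball <- array(as.numeric(d2 <= 100), c(box, box, box))
  sm <- gaussian_smooth_volume(ball, 1)
  mesh2 <- isosurface(sm, level = 0.5)
  rad <- sqrt(rowSums((mesh2$vertices - c0)^2))
  expect_true(all(abs(rad - 10) < 1))

  # orientation consistency: every directed edge used once (single layer)
  f <- mesh2$faces
  ed <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  expect_false(any(duplicated(paste(ed[, 1], ed[, 2]))))

  expect_error(isosurface(vol, level = 2), "empty")
})

test_that("MRC volumes round-trip and malformed headers error", {
  vol <- segmentation_volume(array(as.numeric(runif(4 * 5 * 6) > 0.6),
                                   c(4, 5, 6)), voxel_size = 1.368)
  path <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(vol, path)
  back <- read_mrc(path)
  expect_equal(back$data, vol$data)
  expect_equal(back$voxel_size, 1.368, tolerance = 1e-6)
  expect_equal(read_mrc(path, voxel_size = 2)$voxel_size, 2)

  # anisotropic cell -> error: patch the y cell length in the header
  raw <- readBin(path, "raw", file.size(path))
  con <- file(path, "r+b")
  seek(con, 44, rw = "write")
  writeBin(99.0, con, size = 4L, endian = "little")
  close(con)
  expect_error(read_mrc(path), "anisotropic")

  stub <- withr::local_tempfile(fileext = ".mrc")
  writeBin(raw(10), stub)
  expect_error(read_mrc(stub), "truncated")
})

test_that("compartment surface generation masks and orients correctly", {
  box <- 20
  ax <- seq_len(box) - 1
  c0 <- (box - 1) / 2
  d <- sqrt(outer(outer((ax - c0)^2, (ax - c0)^2, "+"), (ax - c0)^2, "+"))
  membrane <- segmentation_volume(array(as.numeric(d >= 5 & d <= 7),
                                        c(box, box, box)))
  lumen <- segmentation_volume(array(as.numeric(d < 5), c(box, box, box)))
  mesh <- compartment_to_surface(membrane, lumen, smoothing_sigma = 1,
                                 mask_dist = 3)
  # triangles lie within mask_dist of the membrane
  expect_true(all(distance_to_mask(mesh$centroids, membrane) <= 3))
  # normals point into the filled volume (toward the center)
  inward <- matrix(c0, nrow(mesh$centroids), 3) - mesh$centroids
  expect_true(all(rowSums(mesh$normals * inward) > 0))

  expect_error(compartment_to_surface(membrane, NULL), "lumen")
  empty <- segmentation_volume(array(0, c(box, box, box)))
  expect_error(compartment_to_surface(membrane, empty), "lumen")

  # membrane path: fill then extract
  mesh_m <- membrane_to_surface(membrane)
  expect_gt(nrow(mesh_m$faces), 0)
  inward_m <- matrix(c0, nrow(mesh_m$centroids), 3) - mesh_m$centroids
  expect_true(all(rowSums(mesh_m$normals * inward_m) > 0))
})

test_that("surface masking is monotone in the distance threshold", {
  box <- 20
  ax <- seq_len(box) - 1
  c0 <- (box - 1) / 2
  d2 <- outer(outer((ax - c0)^2, (ax - c0)^2, "+"), (ax - c0)^2, "+")
  ball <- array(as.numeric(d2 <= 36), c(box, box, box))
  mesh <- isosurface(gaussian_smooth_volume(ball, 1), 0.5)

  full <- segmentation_volume(array(1, c(box, box, box)))
  expect_identical(mask_surface(mesh, full, 1)$faces, mesh$faces)
  expect_error(mask_surface(mesh, array(0, c(box, box, box)), 1), "empty mask")

  # hemispherical mask keeps only nearby triangles (recheck distances)
  hemi <- array(ball, c(box, box, box))
  hemi[, , seq_len(floor(c0))] <- 0
  kept <- mask_surface(mesh, segmentation_volume(hemi), 0.5)
  expect_true(all(distance_to_mask(kept$centroids, hemi) <= 0.5))

  counts <- vapply(c(0.5, 1, 2, 4),
                   function(dd) nrow(mask_surface(mesh, segmentation_volume(hemi),
                                                  dd)$faces), numeric(1))
  expect_true(all(diff(counts) >= 0))
})
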