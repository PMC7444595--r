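# Binary segmentation volumes: 3-D {0,1} arrays with a (isotropic) voxel size.
# Coordinates are voxel-centered and 0-based: voxel [i, j, k] sits at
# (i-1, j-1, k-1) in voxel units.

#' Construct a binary segmentation volume
#'
#' @param data 3-D array; non-binary values are coerced with `> 0` (a warning is
#'   emitted when coercion changes values).
#' @param voxel_size edge length of a voxel (e.g. nm), `> 0`.
#' @return an object of class `segmentation_volume`.
#' @export
segmentation_volume <- function(data, voxel_size = 1) {
  if (length(dim(data)) != 3L) stop("data must be a 3-D array")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("voxel_size must be a positive scalar")
  if (!all(data %in% c(0, 1))) {
    warning("non-binary volume coerced with > 0 threshold")
    data <- array(as.numeric(data > 0), dim = dim(data))
  } else {
    data <- array(as.numeric(data), dim = dim(data))
  }
  structure(list(data = data, voxel_size = voxel_size),
            class = "segmentation_volume")
}

#' @export
print.segmentation_volume <- function(x, ...) {
  cat(sprintf("<segmentation_volume> %s voxels, %d foreground, voxel size %g\n",
              paste(dim(x$data), collapse = " x "), sum(x$data > 0),
              x$voxel_size))
  invisible(x)
}

#' Gaussian smoothing of a volume
#'
#' Separable 3-D Gaussian convolution (kernel truncated at 4 sigma, renormalized;
#' zero padding at the boundaries). Used to smooth binary masks before
#' isosurface extraction so that the surface is recovered with sub-voxel
#' precision.
#'
#' @param vol 3-D numeric array.
#' @param sigma standard deviation in voxels; `0` returns the input unchanged.
#' @return smoothed array of the same dimensions.
#' @export
gaussian_smooth_volume <- function(vol, sigma) {
  stopifnot(length(dim(vol)) == 3L, sigma >= 0)
  if (sigma == 0) return(vol)
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  conv_axis <- function(a, axis) {
    d <- dim(a)
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- matrix(ap, nrow = dp[1])
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (off in seq(-r, r)) {
      w <- k[off + r + 1]
      src <- seq_len(n) + off
      ok <- src >= 1 & src <= n
      out[ok, ] <- out[ok, ] + w * m[src[ok], , drop = FALSE]
    }
    inv <- order(perm)
    aperm(array(out, dp), inv)
  }
  conv_axis(conv_axis(conv_axis(vol, 1), 2), 3)
}

#' Euclidean distance from points to the nearest foreground voxel
#'
#' Brute-force (chunked) nearest-neighbor distance from arbitrary points (voxel
#' units, 0-based voxel-centered coordinates) to the set of foreground voxels of
#' a mask. Used for masking surfaces with a distance threshold.
#'
#' @param points n x 3 matrix of coordinates (voxel units).
#' @param mask a `segmentation_volume` (or 3-D binary array).
#' @return numeric vector of distances (voxel units); `Inf` if the mask is empty.
#' @export
distance_to_mask <- function(points, mask) {
  data <- if (inherits(mask, "segmentation_volume")) mask$data else mask
  idx <- which(data > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(rep(Inf, nrow(points)))
  vox <- idx - 1 # 0-based voxel centers
  n <- nrow(points)
  out <- numeric(n)
  step <- max(1L, floor(2e7 / nrow(vox)))
  v2 <- rowSums(vox * vox)
  for (start in seq(1L, n, by = step)) {
    sel <- start:min(start + step - 1L, n)
    p <- points[sel, , drop = FALSE]
    # squared distances via the expansion |p - v|^2 = |p|^2 - 2 p.v + |v|^2
    cross <- p %*% t(vox)
    d2 <- outer(rowSums(p * p), v2, "+") - 2 * cross
    best <- max.col(-d2, ties.method = "first")
    out[sel] <- sqrt(pmax(0, d2[cbind(seq_len(nrow(d2)), best)]))
  }
  out
}

#' Read an MRC volume
#'
#' Minimal MRC2014 reader: supports modes 0 (int8), 1 (int16), 2 (float32) and
#' 6 (uint16), little- or big-endian via the machine stamp, and reads the voxel
#' size from the cell dimensions. Anisotropic voxel sizes are not supported.
#' Non-binary data are coerced with a `> 0` threshold (warning).
#'
#' @param path file path.
#' @param voxel_size optional override of the header voxel size.
#' @return a `segmentation_volume`.
#' @export
read_mrc <- function(path, voxel_size = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 1024L)
  if (length(hdr_raw) < 1024L) stop("malformed MRC file: truncated header")
  stamp <- hdr_raw[213:214]
  endian <- if (identical(as.integer(stamp), c(17L, 17L))) "big" else "little"
  int_at <- function(i) readBin(hdr_raw[(4 * (i - 1) + 1):(4 * i)], "integer",
                                1L, size = 4L, endian = endian)
  float_at <- function(i) readBin(hdr_raw[(4 * (i - 1) + 1):(4 * i)], "double",
                                  1L, size = 4L, endian = endian)
  nx <- int_at(1); ny <- int_at(2); nz <- int_at(3)
  mode <- int_at(4)
  mx <- int_at(8); my <- int_at(9); mz <- int_at(10)
  xlen <- float_at(11); ylen <- float_at(12); zlen <- float_at(13)
  nsymbt <- int_at(24)
  if (nx <= 0 || ny <= 0 || nz <= 0) stop("malformed MRC file: bad dimensions")
  if (nsymbt > 0) readBin(con, "raw", nsymbt)
  n <- nx * ny * nz
  vals <- switch(as.character(mode),
    "0" = readBin(con, "integer", n, size = 1L, signed = TRUE, endian = endian),
    "1" = readBin(con, "integer", n, size = 2L, signed = TRUE, endian = endian),
    "2" = readBin(con, "double", n, size = 4L, endian = endian),
    "6" = readBin(con, "integer", n, size = 2L, signed = FALSE, endian = endian),
    stop(sprintf("unsupported MRC mode %d", mode))
  )
  if (length(vals) < n) stop("malformed MRC file: truncated data")
  if (is.null(voxel_size)) {
    vs <- c(if (mx > 0) xlen / mx else 1,
            if (my > 0) ylen / my else 1,
            if (mz > 0) zlen / mz else 1)
    vs[vs == 0] <- 1
    if (max(vs) - min(vs) > 1e-6 * max(vs))
      stop("anisotropic voxel size in MRC header is not supported")
    voxel_size <- vs[1]
  }
  segmentation_volume(array(as.numeric(vals), dim = c(nx, ny, nz)),
                      voxel_size = voxel_size)
}

#' Write a binary volume as MRC (mode 0)
#'
#' @param vol a `segmentation_volume`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(vol, path) {
  stopifnot(inherits(vol, "segmentation_volume"))
  d <- dim(vol$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wi(d) # nx ny nz
  wi(0L) # mode 0: int8
  wi(c(0L, 0L, 0L)) # nxstart
  wi(d) # mx my mz
  wf(d * vol$voxel_size) # cella
  wf(c(90, 90, 90)) # cellb
  wi(c(1L, 2L, 3L)) # mapc mapr maps
  wf(c(0, 1, 1)) # dmin dmax dmean
  wi(0L) # ispg
  wi(0L) # nsymbt
  writeBin(raw(4 * (52 - 24)), con) # extra through word 52
  writeChar("MAP ", con, nchars = 4L, eos = NULL) # word 53
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con) # little-endian stamp
  wf(0) # rms
  wi(0L) # nlabl
  writeBin(raw(800L), con) # labels
  writeBin(as.integer(vol$data > 0), con, size = 1L)
  invisible(path)
}
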