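# VTK XML PolyData (.vtp) I/O, ASCII encoded, written with xml2. Per-triangle
# attributes are stored as CellData arrays; 3-vector attributes (n_v, t_1, t_2)
# as 3-component arrays. Float payloads are printed with 17 significant digits
# so that float64 values round-trip exactly.

fmt_num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
fmt_int <- function(x) paste(format(x, scientific = FALSE, trim = TRUE),
                             collapse = " ")

# columns grouped into 3-component arrays on write
.vec3_arrays <- c(n_v = "n_v", t_1 = "t_1", t_2 = "t_2")

#' Write a triangle mesh as VTK XML PolyData (.vtp)
#'
#' Vertices become Points, faces become Polys; every numeric or logical column
#' of the per-triangle attribute table is written as a CellData array. Column
#' triples `<name>_x/_y/_z` (estimated normals `n_v`, principal directions
#' `t_1`, `t_2`) are grouped into 3-component arrays named `<name>`.
#'
#' @param mesh a `triangle_mesh`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vtp <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  doc <- xml2::xml_new_root("VTKFile", type = "PolyData", version = "1.0",
                            byte_order = "LittleEndian")
  pd <- xml2::xml_add_child(doc, "PolyData")
  m <- nrow(mesh$faces)
  piece <- xml2::xml_add_child(pd, "Piece",
                               NumberOfPoints = as.character(nrow(mesh$vertices)),
                               NumberOfVerts = "0", NumberOfLines = "0",
                               NumberOfStrips = "0",
                               NumberOfPolys = as.character(m))

  pts <- xml2::xml_add_child(piece, "Points")
  da <- xml2::xml_add_child(pts, "DataArray", type = "Float64",
                            Name = "Points", NumberOfComponents = "3",
                            format = "ascii")
  xml2::xml_set_text(da, fmt_num(as.vector(t(mesh$vertices))))

  cd <- xml2::xml_add_child(piece, "CellData")
  dat <- mesh$data
  done <- character(0)
  for (base in names(.vec3_arrays)) {
    cols <- paste0(base, c("_x", "_y", "_z"))
    if (all(cols %in% names(dat))) {
      vals <- t(cbind(dat[[cols[1]]], dat[[cols[2]]], dat[[cols[3]]]))
      a <- xml2::xml_add_child(cd, "DataArray", type = "Float64", Name = base,
                               NumberOfComponents = "3", format = "ascii")
      xml2::xml_set_text(a, fmt_num(as.vector(vals)))
      done <- c(done, cols)
    }
  }
  for (nm in setdiff(names(dat), done)) {
    col <- dat[[nm]]
    if (is.logical(col)) col <- as.integer(col)
    if (!is.numeric(col)) next
    a <- xml2::xml_add_child(cd, "DataArray", type = "Float64", Name = nm,
                             NumberOfComponents = "1", format = "ascii")
    xml2::xml_set_text(a, fmt_num(col))
  }

  polys <- xml2::xml_add_child(piece, "Polys")
  conn <- xml2::xml_add_child(polys, "DataArray", type = "Int64",
                              Name = "connectivity", format = "ascii")
  xml2::xml_set_text(conn, fmt_int(as.vector(t(mesh$faces)) - 1L))
  offs <- xml2::xml_add_child(polys, "DataArray", type = "Int64",
                              Name = "offsets", format = "ascii")
  xml2::xml_set_text(offs, fmt_int(seq_len(m) * 3L))

  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a triangle mesh from VTK XML PolyData (.vtp)
#'
#' Supports ASCII-format files as written by [write_vtp()] (and other tools
#' writing ascii PolyData with triangle Polys). CellData arrays become columns
#' of the per-triangle attribute table; 3-component arrays `n_v`, `t_1`, `t_2`
#' are split back into `_x/_y/_z` columns.
#'
#' @param path input path.
#' @return a `triangle_mesh`.
#' @export
read_vtp <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "VTKFile" ||
        xml2::xml_attr(doc, "type") != "PolyData")
    stop("not a VTK XML PolyData (.vtp) file")
  piece <- xml2::xml_find_first(doc, ".//Piece")
  num <- function(node) as.numeric(strsplit(trimws(xml2::xml_text(node)),
                                            "\\s+")[[1]])
  pts_node <- xml2::xml_find_first(piece, "./Points/DataArray")
  if (is.na(xml2::xml_attr(pts_node, "format")) ||
        xml2::xml_attr(pts_node, "format") != "ascii")
    stop("only ascii-format .vtp files are supported")
  verts <- matrix(num(pts_node), ncol = 3, byrow = TRUE)
  conn <- xml2::xml_find_first(piece,
                               "./Polys/DataArray[@Name='connectivity']")
  offs <- xml2::xml_find_first(piece, "./Polys/DataArray[@Name='offsets']")
  offsets <- num(offs)
  if (any(diff(c(0, offsets)) != 3))
    stop("only pure triangle meshes are supported")
  faces <- matrix(num(conn), ncol = 3, byrow = TRUE) + 1L

  dat <- tibble::tibble(.rows = nrow(faces))
  normals <- NULL
  for (a in xml2::xml_find_all(piece, "./CellData/DataArray")) {
    nm <- xml2::xml_attr(a, "Name")
    ncomp <- xml2::xml_attr(a, "NumberOfComponents")
    vals <- num(a)
    if (!is.na(ncomp) && ncomp == "3") {
      mat <- matrix(vals, ncol = 3, byrow = TRUE)
      dat[[paste0(nm, "_x")]] <- mat[, 1]
      dat[[paste0(nm, "_y")]] <- mat[, 2]
      dat[[paste0(nm, "_z")]] <- mat[, 3]
    } else {
      dat[[nm]] <- vals
    }
  }
  mesh <- triangle_mesh(verts, faces)
  mesh$data <- dat
  mesh
}
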