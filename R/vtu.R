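# Minimal ASCII VTU (VTK unstructured grid) writer/reader for triangle
# meshes with point-data arrays. Enough for inspection in ParaView and for
# round-trip tests; not a general VTK implementation.

#' Write a mesh with point-data fields to an ASCII VTU file
#'
#' @param mesh an `sf_mesh`.
#' @param fields named list of point-data arrays: numeric vectors (scalars)
#'   or n x 2 matrices (written as 3-component vectors with z = 0).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, fields = list(), path) {
  np <- nrow(mesh$nodes); nc <- nrow(mesh$tri)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  num <- function(x) paste(formatC(x, format = "g", digits = 9), collapse = " ")
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid>')
  w(sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', np, nc))
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w(num(as.vector(t(cbind(mesh$nodes, 0)))))
  w('</DataArray></Points>')
  w('<Cells>')
  w('<DataArray type="Int32" Name="connectivity" format="ascii">')
  w(paste(as.vector(t(mesh$tri)) - 1L, collapse = " "))
  w('</DataArray>')
  w('<DataArray type="Int32" Name="offsets" format="ascii">')
  w(paste(seq_len(nc) * 3L, collapse = " "))
  w('</DataArray>')
  w('<DataArray type="UInt8" Name="types" format="ascii">')
  w(paste(rep(5L, nc), collapse = " "))
  w('</DataArray>')
  w('</Cells>')
  if (length(fields)) {
    w('<PointData>')
    for (nm in names(fields)) {
      f <- fields[[nm]]
      if (is.matrix(f)) {
        stopifnot(nrow(f) == np)
        w(sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="3" format="ascii">', nm))
        w(num(as.vector(t(cbind(f, 0)))))
      } else {
        stopifnot(length(f) == np)
        w(sprintf('<DataArray type="Float64" Name="%s" format="ascii">', nm))
        w(num(f))
      }
      w('</DataArray>')
    }
    w('</PointData>')
  }
  w('</Piece>')
  w('</UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}

#' Read back an ASCII VTU file written by [write_vtu()]
#'
#' @param path file path.
#' @return list with `nodes`, `tri` and named point-data `fields`.
#' @export
read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  np <- as.integer(xml2::xml_attr(piece, "NumberOfPoints"))
  getnum <- function(node) as.numeric(strsplit(trimws(xml2::xml_text(node)), "\\s+")[[1]])
  pts <- getnum(xml2::xml_find_first(piece, ".//Points/DataArray"))
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)[, 1:2, drop = FALSE]
  conn <- getnum(xml2::xml_find_first(
    piece, ".//Cells/DataArray[@Name=\"connectivity\"]"))
  tri <- matrix(as.integer(conn), ncol = 3, byrow = TRUE) + 1L
  fields <- list()
  for (da in xml2::xml_find_all(piece, ".//PointData/DataArray")) {
    nm <- xml2::xml_attr(da, "Name")
    ncomp <- xml2::xml_attr(da, "NumberOfComponents")
    v <- getnum(da)
    fields[[nm]] <- if (!is.na(ncomp) && as.integer(ncomp) == 3)
      matrix(v, ncol = 3, byrow = TRUE)[, 1:2, drop = FALSE] else v
  }
  list(nodes = nodes, tri = tri, fields = fields)
}
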