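# Minimal ASCII VTU (VTK XML unstructured grid) I/O for hexahedral meshes:
# region labels and fiber vectors as cell data, displacements as point data.

region_codes <- c(healthy = 0L, border = 1L, infarct = 2L, patch = 3L)

#' Write a mesh (and optional fields) to an ASCII VTU file
#'
#' Cell data: `region` (0 healthy, 1 border, 2 infarct, 3 patch) and, when a
#' fiber field is given, element-mean `f0`, `s0`, `n0` vectors. Point data:
#' nodal displacements when a simulation is given.
#'
#' @param mesh an `lv_mesh`
#' @param file output path
#' @param fibers optional `fiber_field`
#' @param sim optional `lv_sim` (writes `displacement` point data)
#' @return `file`, invisibly
#' @export
write_vtu <- function(mesh, file, fibers = NULL, sim = NULL) {
  n <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  num <- function(x) paste(format(x, digits = 10, scientific = FALSE,
                                  trim = TRUE), collapse = " ")
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid>')
  w(sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', n, ne))
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w(num(t(mesh$nodes)))
  w('</DataArray></Points>')
  w('<Cells>')
  w('<DataArray type="Int64" Name="connectivity" format="ascii">')
  w(num(t(mesh$elems) - 1L))
  w('</DataArray>')
  w('<DataArray type="Int64" Name="offsets" format="ascii">')
  w(num(8L * seq_len(ne)))
  w('</DataArray>')
  w('<DataArray type="UInt8" Name="types" format="ascii">')
  w(num(rep(12L, ne)))
  w('</DataArray>')
  w('</Cells>')
  w('<CellData>')
  w('<DataArray type="Int32" Name="region" format="ascii">')
  w(num(region_codes[mesh$region]))
  w('</DataArray>')
  if (!is.null(fibers)) {
    for (nm in c("f0", "s0", "n0")) {
      v <- fibers[[nm]]
      em <- t(vapply(seq_len(ne), function(e)
        colMeans(v[(e - 1) * 8 + 1:8, , drop = FALSE]), numeric(3)))
      w(sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="3" format="ascii">', nm))
      w(num(t(em)))
      w('</DataArray>')
    }
  }
  w('</CellData>')
  w('<PointData>')
  if (!is.null(sim)) {
    w('<DataArray type="Float64" Name="displacement" NumberOfComponents="3" format="ascii">')
    w(num(t(sim$u)))
    w('</DataArray>')
  }
  w('</PointData>')
  w('</Piece>')
  w('</UnstructuredGrid>')
  w('</VTKFile>')
  invisible(file)
}

#' Write a converged load path as a VTU series
#'
#' One ASCII VTU file per stored increment (`<prefix>_0000.vtu`, ...), each
#' with the nodal displacement of that increment, plus the pressure curve
#' table as `<prefix>_curves.csv`.
#'
#' @param mesh an `lv_mesh`
#' @param sim an `lv_sim` solved with `store_increments = TRUE`
#' @param prefix output path prefix
#' @param fibers optional `fiber_field` written into each file
#' @return the file paths, invisibly
#' @export
write_vtu_series <- function(mesh, sim, prefix, fibers = NULL) {
  if (is.null(sim$increments))
    stop("simulation was run with store_increments = FALSE", call. = FALSE)
  files <- character(0)
  for (i in seq_along(sim$increments)) {
    f <- sprintf("%s_%04d.vtu", prefix, i - 1)
    step <- sim$increments[[i]]
    fake <- list(u = step$u)
    write_vtu(mesh, f, fibers = fibers, sim = fake)
    files <- c(files, f)
  }
  cf <- paste0(prefix, "_curves.csv")
  write.csv(sim$curves, cf, row.names = FALSE)
  invisible(c(files, cf))
}

#' Read an ASCII VTU file written by [write_vtu()]
#'
#' Minimal reader for hexahedral ASCII VTU: nodes, connectivity, region
#' labels and any vector fields present.
#'
#' @param file path
#' @return list with `nodes`, `elems` (1-based), `region` and a `fields`
#'   list of any additional data arrays
#' @export
read_vtu <- function(file) {
  doc <- xml2::read_xml(file)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  n <- as.integer(xml2::xml_attr(piece, "NumberOfPoints"))
  ne <- as.integer(xml2::xml_attr(piece, "NumberOfCells"))
  getvals <- function(node)
    as.numeric(strsplit(trimws(xml2::xml_text(node)), "\\s+")[[1]])
  pts <- getvals(xml2::xml_find_first(piece, ".//Points/DataArray"))
  nodes <- matrix(pts, n, 3, byrow = TRUE)
  conn <- getvals(xml2::xml_find_first(
    piece, ".//Cells/DataArray[@Name='connectivity']"))
  elems <- matrix(as.integer(conn), ne, 8, byrow = TRUE) + 1L
  types <- getvals(xml2::xml_find_first(
    piece, ".//Cells/DataArray[@Name='types']"))
  if (!all(types == 12))
    stop("only hexahedral (type 12) VTU meshes are supported", call. = FALSE)
  region <- NULL
  fields <- list()
  for (da in xml2::xml_find_all(piece, ".//CellData/DataArray")) {
    nm <- xml2::xml_attr(da, "Name")
    vals <- getvals(da)
    if (nm == "region") {
      region <- names(region_codes)[match(as.integer(vals), region_codes)]
    } else {
      nc <- as.integer(xml2::xml_attr(da, "NumberOfComponents"))
      if (is.na(nc)) nc <- 1L
      fields[[nm]] <- if (nc > 1) matrix(vals, ncol = nc, byrow = TRUE) else vals
    }
  }
  for (da in xml2::xml_find_all(piece, ".//PointData/DataArray")) {
    nm <- xml2::xml_attr(da, "Name")
    nc <- as.integer(xml2::xml_attr(da, "NumberOfComponents"))
    if (is.na(nc)) nc <- 1L
    vals <- getvals(da)
    fields[[nm]] <- if (nc > 1) matrix(vals, ncol = nc, byrow = TRUE) else vals
  }
  list(nodes = nodes, elems = elems, region = region, fields = fields)
}
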