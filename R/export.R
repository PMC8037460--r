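#' Export a mesh (with optional nodal fields) to legacy VTK
#'
#' Writes an ASCII legacy `.vtk` unstructured grid: triangle connectivity,
#' the subdomain tag as cell data, and any nodal fields (e.g. temperature,
#' velocity components) as point data.
#'
#' @param mesh an `ac_mesh`.
#' @param file output path.
#' @param point_data named list of nodal vectors.
#' @return `file`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, file, point_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$tri)
  con <- file(file, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "anterior chamber mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", n, "double")), con)
  utils::write.table(cbind(mesh$nodes, 0), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(paste("CELLS", m, 4 * m), con)
  utils::write.table(cbind(3L, mesh$tri - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(paste("CELL_TYPES", m), con)
  writeLines(as.character(rep(5L, m)), con)
  writeLines(c(paste("CELL_DATA", m),
               "SCALARS subdomain int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(mesh$subdomain == "porous")), con)
  if (length(point_data)) {
    writeLines(paste("POINT_DATA", n), con)
    for (nm in names(point_data)) {
      writeLines(c(paste("SCALARS", nm, "double 1"),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(point_data[[nm]], digits = 10), con)
    }
  }
  invisible(file)
}

#' Export a mesh to Gmsh MSH 2.2 ASCII
#'
#' Boundary edges are written as 2-node line elements carrying their tag as
#' a named physical group; triangles carry the bulk/porous subdomain.
#'
#' @param mesh an `ac_mesh`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_mesh_msh <- function(mesh, file) {
  con <- file(file, "w"); on.exit(close(con))
  tags <- sort(unique(mesh$boundary$tag))
  phys <- stats::setNames(seq_along(tags), tags)
  sub_id <- c(bulk = length(tags) + 1L, porous = length(tags) + 2L)
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$PhysicalNames", as.character(length(tags) + 2L)), con)
  for (tg in tags)
    writeLines(sprintf('1 %d "%s"', phys[[tg]], tg), con)
  writeLines(c(sprintf('2 %d "bulk"', sub_id[["bulk"]]),
               sprintf('2 %d "porous"', sub_id[["porous"]]),
               "$EndPhysicalNames", "$Nodes",
               as.character(nrow(mesh$nodes))), con)
  writeLines(sprintf("%d %.12g %.12g 0", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2]), con)
  b <- mesh$boundary
  nelem <- nrow(b) + nrow(mesh$tri)
  writeLines(c("$EndNodes", "$Elements", as.character(nelem)), con)
  writeLines(sprintf("%d 1 2 %d %d %d %d", seq_len(nrow(b)),
                     phys[b$tag], phys[b$tag], b$n1, b$n2), con)
  sid <- sub_id[mesh$subdomain]
  writeLines(sprintf("%d 2 2 %d %d %d %d %d",
                     nrow(b) + seq_len(nrow(mesh$tri)), sid, sid,
                     mesh$tri[, 1], mesh$tri[, 2], mesh$tri[, 3]), con)
  writeLines("$EndElements", con)
  invisible(file)
}

#' Write a probe trace as CSV
#'
#' Columns `time`, `value`, `reference`.
#'
#' @param trace a `probe_trace`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_trace_csv <- function(trace, file) {
  utils::write.csv(data.frame(time = trace$times, value = trace$values,
                              reference = trace$reference),
                   file, row.names = FALSE)
  invisible(file)
}

#' Write scenario results (or any list/table) as JSON
#'
#' @param x object to serialize.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_results_json <- function(x, file) {
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(file)
}
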