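# Legacy ASCII VTK export of labelled quad meshes with cell/point data.

#' Write a mesh (with optional fields) as a legacy ASCII VTK file
#'
#' @param mesh a `mesh_model`.
#' @param path output file (conventionally `.vtk`).
#' @param cell_data named list of per-element vectors.
#' @param point_data named list of per-node vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, cell_data = list(), point_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("ossify mesh snapshot")
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl("POINTS %d double", n)
  writeLines(sprintf("%.9g %.9g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  wl("CELLS %d %d", m, 5L * m)
  writeLines(sprintf("4 %d %d %d %d", mesh$elems[, 1] - 1L,
                     mesh$elems[, 2] - 1L, mesh$elems[, 3] - 1L,
                     mesh$elems[, 4] - 1L), con)
  wl("CELL_TYPES %d", m)
  writeLines(rep("9", m), con)                      # VTK_QUAD
  if (length(cell_data)) {
    wl("CELL_DATA %d", m)
    for (nm in names(cell_data)) {
      wl("SCALARS %s double 1", nm)
      wl("LOOKUP_TABLE default")
      writeLines(sprintf("%.9g", as.numeric(cell_data[[nm]])), con)
    }
  }
  if (length(point_data)) {
    wl("POINT_DATA %d", n)
    for (nm in names(point_data)) {
      wl("SCALARS %s double 1", nm)
      wl("LOOKUP_TABLE default")
      writeLines(sprintf("%.9g", as.numeric(point_data[[nm]])), con)
    }
  }
  invisible(path)
}
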