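# Legacy-VTK structured-grid export of meshes and concentration fields, for
# inspection in ParaView and friends.

#' Write a mesh and cell fields to a legacy VTK structured grid
#'
#' Writes the full `(r, z)` grid (one layer thick in the third coordinate)
#' as an ASCII `STRUCTURED_GRID` with cell data: the integer region label
#' (`0` void, `1` balloon, `2` plaque, `3` wall) and any supplied per-cell
#' fields, padded with zeros on void cells.
#'
#' @param mesh An `axi_mesh`.
#' @param path Output file path.
#' @param fields Named list of numeric vectors over the active cells.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, fields = list()) {
  if (!inherits(mesh, "axi_mesh")) {
    dcb_abort("'mesh' must be an 'axi_mesh'", "dcb_validation_error")
  }
  np_r <- mesh$nr + 1L
  np_z <- mesh$nz + 1L
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "dcbsim axisymmetric (r,z) slice",
               "ASCII",
               "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d 1", np_r, np_z),
               sprintf("POINTS %d double", np_r * np_z)), con)
  pts <- expand.grid(r = mesh$r_edges, z = mesh$z_edges)
  writeLines(sprintf("%.9g %.9g 0", pts$r, pts$z), con)
  ncell <- mesh$nr * mesh$nz
  writeLines(sprintf("CELL_DATA %d", ncell), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", as.integer(mesh$region)), con)
  for (nm in names(fields)) {
    full <- numeric(ncell)
    full[which(!is.na(mesh$active))] <- fields[[nm]][mesh$active[!is.na(mesh$active)]]
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", full), con)
  }
  invisible(path)
}
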