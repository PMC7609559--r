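#' Write a flow field as a legacy VTK structured grid
#'
#' Serializes the cell-centre grid of a [solve_steady_flow()] field to an
#' ASCII legacy-VTK `STRUCTURED_GRID` file with point data `velocity`
#' (axial, radial, 0), `pressure` (Pa) and `viscosity` (Pa s), for
#' inspection in standard scientific visualization tools.
#'
#' @param field a `flow_field`.
#' @param path output path (conventionally `.vtk`).
#' @return `path`, invisibly.
#' @export
write_vtk_field <- function(field, path) {
  stopifnot(inherits(field, "flow_field"))
  mesh <- field$mesh
  nz <- mesh$nz; nr <- mesh$nr
  u_cc <- 0.5 * (field$u[-1, , drop = FALSE] +
                 field$u[-(nz + 1), , drop = FALSE])
  v_cc <- 0.5 * (field$v[, -1, drop = FALSE] +
                 field$v[, -(nr + 1), drop = FALSE])
  r <- outer(mesh$R_c, mesh$eta_c)
  z <- matrix(mesh$z_c, nz, nr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "axisymmetric stenotic aorta flow field",
               "ASCII",
               "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d 1", nz, nr),
               sprintf("POINTS %d double", nz * nr)), con)
  writeLines(sprintf("%.9g %.9g 0", as.numeric(z), as.numeric(r)), con)
  writeLines(c(sprintf("POINT_DATA %d", nz * nr),
               "VECTORS velocity double"), con)
  writeLines(sprintf("%.9g %.9g 0", as.numeric(u_cc), as.numeric(v_cc)), con)
  writeLines(c("SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.9g", as.numeric(field$p)), con)
  writeLines(c("SCALARS viscosity double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.9g", as.numeric(field$mu)), con)
  invisible(path)
}
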