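#' Write a synthetic patient's measurement planes to disk
#'
#' One CSV per plane (named `<condition>_<station>.csv`, columns
#' `x, y, vx, vy, vz, mask`) plus a `manifest.json` recording the patient
#' id, the velocity-encoding limit, per-plane target flows and the
#' generating ground-truth parameters.
#'
#' @param patient a [sample_patient()] result with planes.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_patient_planes <- function(patient, dir) {
  stopifnot(inherits(patient, "synthetic_patient"))
  if (is.null(patient$planes)) {
    stop("patient was sampled without measurement planes", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(id = patient$id, venc = patient$venc,
                   ground_truth = patient$ground_truth, planes = list())
  for (cond in names(patient$planes)) {
    for (st in names(patient$planes[[cond]])) {
      fn <- sprintf("%s_%s.csv", cond, st)
      pl <- patient$planes[[cond]][[st]]
      write_velocity_plane(pl, file.path(dir, fn))
      manifest$planes[[paste(cond, st, sep = "_")]] <-
        list(file = fn, condition = cond, station = st,
             q_mls = plane_flow(pl), radius = pl$radius)
    }
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize a boundary-condition set to JSON
#'
#' Writes the inlet profile table (node radii and velocities, the
#' renormalization factor and source plane) and, if present, the sink band
#' (axial extent, normal velocity, extracted flux) for a given mesh.
#'
#' @param mesh the `axi_mesh` the inlet profile was built for.
#' @param bcs list with `inlet` (an [inlet_profile()]) and optionally
#'   `sink` (a [build_sink_band()] result).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bcs_json <- function(mesh, bcs, path) {
  stopifnot(inherits(mesh, "axi_mesh"), inherits(bcs$inlet, "inlet_profile"))
  out <- list(
    inlet = list(radius_m = mesh$eta_c * mesh$R_f[1],
                 u_m_s = bcs$inlet$u, q_mls = bcs$inlet$q_mls,
                 renormalization_factor = bcs$inlet$factor,
                 source = bcs$inlet$source))
  if (!is.null(bcs$sink)) {
    out$sink <- list(band_m = bcs$sink$band, v_n_m_s = bcs$sink$v_n,
                     q_mls = bcs$sink$q_mls, area_m2 = bcs$sink$area)
    out$outlet <- list(q_mls = bcs$inlet$q_mls - bcs$sink$q_mls)
  } else {
    out$outlet <- list(q_mls = bcs$inlet$q_mls)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
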