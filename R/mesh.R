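#' Mesh sizing rules
#'
#' Sizing rules for the graded structured grid: a base cell size `delta`
#' (default 0.4 mm), a wall boundary layer of `n_wall_layers` cells whose
#' total thickness is one third of the base cell size with each layer 50
#' percent thicker than the one beneath it (so for three layers the
#' thicknesses are \eqn{t, 1.5t, 2.25t} with \eqn{4.75\,t = \Delta/3}), and
#' axial refinement down to `min_cell` (default 0.1 mm) where the wall slope
#' `|dr/dz|` exceeds `slope_threshold`.
#'
#' @param delta base cell size, m.
#' @param n_wall_layers number of wall boundary layers.
#' @param growth layer-to-layer growth ratio.
#' @param min_cell minimum axial cell size under refinement, m.
#' @param slope_threshold wall slope `|dr/dz|` beyond which axial spacing is
#'   refined.
#' @return An object of class `mesh_spec` with the derived layer thicknesses
#'   (element `layers`, ordered from the wall inward).
#' @examples
#' spec <- mesh_spec()
#' spec$layers * 1e6   # 28.07, 42.11, 63.16 micrometres
#' @export
mesh_spec <- function(delta = 0.4e-3, n_wall_layers = 3, growth = 1.5,
                      min_cell = 0.1e-3, slope_threshold = 0.5) {
  stopifnot(delta > 0, n_wall_layers >= 1, growth > 1,
            min_cell > 0, min_cell <= delta, slope_threshold > 0)
  t0 <- (delta / 3) / sum(growth^(seq_len(n_wall_layers) - 1))
  layers <- t0 * growth^(seq_len(n_wall_layers) - 1)
  stopifnot(abs(sum(layers) - delta / 3) < 1e-15)
  structure(
    list(delta = delta, n_wall_layers = n_wall_layers, growth = growth,
         min_cell = min_cell, slope_threshold = slope_threshold,
         layers = layers),
    class = "mesh_spec"
  )
}

#' Generate a graded axisymmetric structured mesh
#'
#' Builds a body-fitted structured grid for a [build_vessel()] geometry in
#' mapped coordinates \eqn{(z, \eta)} with \eqn{\eta = r / r(z) \in [0, 1]}:
#' radial faces carry the wall boundary layers (physical thickness per
#' [mesh_spec()] at the reference radius, scaling with the local radius
#' inside the stenosis) above a uniform core at approximately `delta`; axial
#' faces are spaced at `delta`, refined towards `min_cell` where the wall
#' slope exceeds the spec threshold. Cell volumes use the axisymmetric
#' \eqn{2\pi r} weight (midpoint rule in z).
#'
#' @param geometry a `vessel_geometry`.
#' @param spec a `mesh_spec`.
#' @return An object of class `axi_mesh`: face/centre coordinates in both
#'   directions, the local radius and wall slope, cell volumes, and the
#'   indices of the wall-layer cells.
#' @export
generate_mesh <- function(geometry, spec = mesh_spec()) {
  stopifnot(inherits(geometry, "vessel_geometry"), inherits(spec, "mesh_spec"))
  r_ref <- geometry$r_ref
  core_extent <- r_ref - spec$delta / 3
  if (core_extent <= 2 * spec$delta) {
    stop("vessel radius too small to fit the wall layers over a core grid",
         call. = FALSE)
  }
  if (geometry$length < 3 * spec$delta) {
    stop("vessel too short for the requested cell size", call. = FALSE)
  }
  # radial faces in eta; wall layers prescribed in physical units at r_ref
  n_core <- max(2L, round(core_extent / spec$delta))
  eta_core <- seq(0, core_extent / r_ref, length.out = n_core + 1)
  eta_wall <- (r_ref - rev(cumsum(spec$layers))[-1]) / r_ref
  eta_f <- c(eta_core, eta_wall, 1)
  stopifnot(all(diff(eta_f) > 0))
  nr <- length(eta_f) - 1L

  # axial faces: march with slope-refined target spacing
  h_of <- function(z) {
    s <- abs(vessel_radius(geometry, z, deriv = TRUE))
    if (s <= spec$slope_threshold) spec$delta
    else max(spec$min_cell, spec$delta * spec$slope_threshold / s)
  }
  z_f <- 0
  z <- 0
  while (z < geometry$length - 1e-12) {
    h <- h_of(z + h_of(z) / 2)
    if (geometry$length - z < 1.5 * h) h <- geometry$length - z
    z <- min(z + h, geometry$length)
    z_f <- c(z_f, z)
  }
  nz <- length(z_f) - 1L

  z_c <- (z_f[-1] + z_f[-length(z_f)]) / 2
  eta_c <- (eta_f[-1] + eta_f[-length(eta_f)]) / 2
  R_f <- vessel_radius(geometry, z_f)
  R_c <- vessel_radius(geometry, z_c)
  dRdz_f <- vessel_radius(geometry, z_f, deriv = TRUE)
  dRdz_c <- vessel_radius(geometry, z_c, deriv = TRUE)
  dz <- diff(z_f)
  # volumes: V_ij = pi R(zc_i)^2 (eta_j^2 - eta_{j-1}^2) dz_i  (midpoint in z)
  deta2 <- diff(eta_f^2)
  vol <- outer(pi * R_c^2 * dz, deta2)
  stopifnot(all(vol > 0))

  structure(
    list(nz = nz, nr = nr, z_f = z_f, z_c = z_c, dz = dz,
         eta_f = eta_f, eta_c = eta_c, deta = diff(eta_f),
         R_f = R_f, R_c = R_c, dRdz_f = dRdz_f, dRdz_c = dRdz_c,
         vol = vol,
         wall_layer_cells = (nr - spec$n_wall_layers + 1L):nr,
         geometry = geometry, spec = spec),
    class = "axi_mesh"
  )
}

#' @export
print.axi_mesh <- function(x, ...) {
  cat(sprintf("<axi_mesh> %d x %d cells (axial x radial), %d wall layers\n",
              x$nz, x$nr, x$spec$n_wall_layers))
  invisible(x)
}

#' Total mesh volume
#'
#' Sum of all axisymmetric cell volumes; approximates the solid-of-revolution
#' volume \eqn{\pi \int r(z)^2 dz} of the vessel.
#'
#' @param mesh an `axi_mesh`.
#' @return volume, m^3.
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "axi_mesh"))
  sum(mesh$vol)
}

#' Physical thickness of the wall-layer cells
#'
#' Wall-layer thicknesses at a given axial position (they scale with the
#' local radius; at the reference radius they equal the [mesh_spec()]
#' layers exactly).
#'
#' @param mesh an `axi_mesh`.
#' @param z axial position, m (default inlet).
#' @return numeric vector ordered from the wall inward, m.
#' @export
wall_layer_thickness <- function(mesh, z = 0) {
  R <- vessel_radius(mesh$geometry, z)
  rev(diff(mesh$eta_f)[mesh$wall_layer_cells]) * R
}
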