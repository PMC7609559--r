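#' Parametric axisymmetric stenotic vessel
#'
#' A reduced-order stand-in for a segmented patient aorta: a straightened
#' axisymmetric tube of reference radius `r_ref` with a smooth cosine-bump
#' narrowing of diameter-based degree `d` centred at `z_s`. The radius
#' profile is
#' \deqn{r(z) = R_{ref} (1 - D\, w(z)),\qquad
#'       w(z) = \tfrac12\left(1 + \cos\frac{2\pi (z - z_s)}{l_s}\right)}
#' on the support \eqn{|z - z_s| \le l_s/2} and \eqn{w = 0} elsewhere, which
#' is continuously differentiable with minimum radius \eqn{R_{ref}(1-D)} at
#' the throat. The axial coordinate runs from the sinotubular junction
#' (inlet, `z = 0`) downstream; all lengths are metres.
#'
#' @param r_ref reference (unstenosed) radius, m.
#' @param d diameter-based degree of stenosis in `[0, 1)`; for an
#'   axisymmetric vessel the diameter and radius ratios coincide.
#' @param length vessel length, m.
#' @param l_s stenosis length (support of the bump), m.
#' @param z_s stenosis centre, m.
#' @param branch_band numeric length-2, axial band `[z_b0, z_b1]` on the wall
#'   where aortic-arch branch outflow is extracted (see [build_sink_band()]).
#' @param stations named numeric vector of measurement-plane stations; the
#'   default places the sinotubular junction at the inlet, the mid-ascending
#'   plane halfway to the branch band, and the descending plane downstream of
#'   the stenosis.
#' @return An object of class `vessel_geometry`.
#' @examples
#' v <- build_vessel(r_ref = 0.01, d = 0.5)
#' degree_of_stenosis(v)  # 0.5
#' @export
build_vessel <- function(r_ref = 0.012, d = 0.351, length = 0.15,
                         l_s = 0.03, z_s = 0.10,
                         branch_band = c(0.05, 0.08),
                         stations = NULL) {
  if (!is.finite(r_ref) || r_ref <= 0) stop("r_ref must be > 0", call. = FALSE)
  if (!is.finite(d) || d < 0 || d >= 1) {
    stop("degree of stenosis d must lie in [0, 1)", call. = FALSE)
  }
  if (length <= 0 || l_s <= 0) stop("length and l_s must be > 0", call. = FALSE)
  if (z_s - l_s / 2 < 0 || z_s + l_s / 2 > length) {
    stop("stenosis support must lie inside [0, length]", call. = FALSE)
  }
  if (!is.numeric(branch_band) || base::length(branch_band) != 2 ||
      branch_band[1] >= branch_band[2] ||
      branch_band[1] < 0 || branch_band[2] > length) {
    stop("branch_band must be an increasing pair inside [0, length]",
         call. = FALSE)
  }
  if (is.null(stations)) {
    stations <- c(sinotubular = 0,
                  mid_ascending = branch_band[1] / 2,
                  descending = (z_s + l_s / 2 + length) / 2)
  }
  structure(
    list(r_ref = r_ref, d = d, length = length, l_s = l_s, z_s = z_s,
         branch_band = branch_band, stations = stations),
    class = "vessel_geometry"
  )
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat(sprintf(
    "<vessel_geometry> R_ref %.1f mm, stenosis %.1f%% at z = %.0f mm (l_s %.0f mm), L %.0f mm\n",
    1e3 * x$r_ref, 100 * x$d, 1e3 * x$z_s, 1e3 * x$l_s, 1e3 * x$length))
  invisible(x)
}

#' Radius profile of a vessel
#'
#' Evaluates \eqn{r(z)} (and optionally \eqn{dr/dz}) of a
#' [build_vessel()] geometry.
#'
#' @param geometry a `vessel_geometry`.
#' @param z axial positions, m.
#' @param deriv if `TRUE` return the slope `dr/dz` instead of the radius.
#' @return numeric vector, m (or dimensionless slope).
#' @export
vessel_radius <- function(geometry, z, deriv = FALSE) {
  stopifnot(inherits(geometry, "vessel_geometry"))
  phase <- 2 * pi * (z - geometry$z_s) / geometry$l_s
  inside <- abs(z - geometry$z_s) <= geometry$l_s / 2
  if (deriv) {
    dw <- ifelse(inside, -pi / geometry$l_s * sin(phase), 0)
    -geometry$r_ref * geometry$d * dw
  } else {
    w <- ifelse(inside, 0.5 * (1 + cos(phase)), 0)
    geometry$r_ref * (1 - geometry$d * w)
  }
}

#' Diameter-based degree of stenosis
#'
#' Evaluates \eqn{1 - \min_z r(z) / R_{ref}} by numerical minimisation of the
#' radius profile (identical to the diameter-based definition in an
#' axisymmetric vessel).
#'
#' @param geometry a `vessel_geometry`.
#' @return fraction in `[0, 1)`.
#' @export
degree_of_stenosis <- function(geometry) {
  stopifnot(inherits(geometry, "vessel_geometry"))
  if (geometry$d == 0) return(0)
  opt <- stats::optimize(function(z) vessel_radius(geometry, z),
                         lower = geometry$z_s - geometry$l_s / 2,
                         upper = geometry$z_s + geometry$l_s / 2,
                         tol = 1e-12)
  1 - opt$objective / geometry$r_ref
}
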