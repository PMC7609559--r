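#' Transstenotic pressure gradient
#'
#' Clinical pressure gradient across the narrowing: the upstream pressure
#' P1 is the area-averaged static pressure on the inlet plane (sinotubular
#' junction), the downstream pressure P2 is taken where the pressure
#' recovery of the decelerating post-stenotic jet is maximal, i.e. the
#' maximum area-averaged pressure over all planes downstream of the throat.
#' The gradient (P1 - P2) is reported in mmHg and floored at zero.
#'
#' The result is invariant under adding a constant to the pressure field.
#'
#' @param field a converged `flow_field`.
#' @param geometry the `vessel_geometry` the field was computed on (defaults
#'   to the one carried by the field's mesh).
#' @return pressure gradient, mmHg.
#' @export
pressure_gradient <- function(field, geometry = field$mesh$geometry) {
  stopifnot(inherits(field, "flow_field"))
  if (!field$converged) {
    stop("pressure gradient requires a converged flow field", call. = FALSE)
  }
  mesh <- field$mesh
  deta2 <- diff(mesh$eta_f^2)
  pbar <- as.numeric(field$p %*% deta2) / sum(deta2)   # area average per plane
  p1 <- pbar[1]
  z_throat <- if (geometry$d > 0) geometry$z_s else 0
  down <- which(mesh$z_c > z_throat)
  down <- setdiff(down, 1L)
  if (!length(down)) stop("no plane downstream of the throat", call. = FALSE)
  p2 <- max(pbar[down])
  max(0, (p1 - p2)) / unit_conventions$pa_per_mmhg
}

#' Surface-averaged wall shear stress
#'
#' Area-weighted mean of the wall shear stress over a wall segment, with
#' axisymmetric arc weights \eqn{2\pi r \sqrt{1 + r'^2}\, dz}. The default
#' segment is the ascending aorta, from the inlet to the start of the
#' branch band.
#'
#' @param field a converged `flow_field`.
#' @param segment numeric length-2 axial interval `[z0, z1]`, m.
#' @return mean wall shear stress, Pa.
#' @export
surface_averaged_wss <- function(field, segment = NULL) {
  stopifnot(inherits(field, "flow_field"))
  if (!field$converged) {
    stop("wall shear requires a converged flow field", call. = FALSE)
  }
  mesh <- field$mesh
  if (is.null(segment)) segment <- c(0, mesh$geometry$branch_band[1])
  stopifnot(length(segment) == 2, segment[1] < segment[2])
  sel <- mesh$z_c >= segment[1] & mesh$z_c <= segment[2]
  if (!any(sel)) stop("empty wall segment", call. = FALSE)
  w <- 2 * pi * mesh$R_c[sel] * sqrt(1 + mesh$dRdz_c[sel]^2) * mesh$dz[sel]
  sum(field$wall_tau[sel] * w) / sum(w)
}

#' Secondary flow degree
#'
#' Ratio between the mean in-plane velocity magnitude and the mean
#' through-plane velocity over the lumen.
#'
#' @param plane a [velocity_plane()].
#' @param eps smallest admissible mean through-plane velocity, m/s; below
#'   this the metric is undefined (near-zero net flow) and an error is
#'   raised.
#' @return dimensionless SFD.
#' @export
secondary_flow_degree <- function(plane, eps = 1e-6) {
  stopifnot(inherits(plane, "velocity_plane"))
  vbar <- mean(plane$vz[plane$mask])
  if (!is.finite(vbar) || vbar <= eps) {
    stop("mean through-plane velocity too small: SFD undefined",
         call. = FALSE)
  }
  mean(sqrt(plane$vx^2 + plane$vy^2)[plane$mask]) / vbar
}

#' Normalized flow displacement
#'
#' Off-centre position of the through-plane flow, normalized by the lumen
#' radius and clipped to `[0, 1]`. The default `"velocity_max"` variant
#' reports the distance from the lumen centre to the location of the
#' maximum through-plane velocity (ties broken by the masked point nearest
#' the centre); the `"flow_centroid"` variant reports the distance to the
#' through-plane-velocity-weighted centroid.
#'
#' @param plane a [velocity_plane()].
#' @param variant `"velocity_max"` (default) or `"flow_centroid"`.
#' @return dimensionless NFD in `[0, 1]`.
#' @export
normalized_flow_displacement <- function(plane,
                                         variant = c("velocity_max",
                                                     "flow_centroid")) {
  stopifnot(inherits(plane, "velocity_plane"))
  variant <- match.arg(variant)
  n <- c(length(plane$x), length(plane$y))
  gx <- outer(plane$x - plane$center[1], rep(1, n[2]))
  gy <- outer(rep(1, n[1]), plane$y - plane$center[2])
  vz <- plane$vz[plane$mask]
  if (all(abs(vz) < 1e-300)) {
    stop("through-plane field is identically zero: NFD undefined",
         call. = FALSE)
  }
  if (variant == "velocity_max") {
    vmax <- max(vz)
    at_max <- plane$mask & plane$vz >= vmax - 1e-12 * max(abs(vmax), 1)
    dist <- sqrt(gx^2 + gy^2)
    d <- min(dist[at_max])
  } else {
    tot <- sum(vz)
    if (abs(tot) < 1e-300) {
      stop("net through-plane flow is zero: flow centroid undefined",
           call. = FALSE)
    }
    cx <- sum((gx[plane$mask]) * vz) / tot
    cy <- sum((gy[plane$mask]) * vz) / tot
    d <- sqrt(cx^2 + cy^2)
  }
  min(max(d / plane$radius, 0), 1)
}

#' Cardiac index
#'
#' Cardiac output (heart rate times stroke volume) normalized by body
#' surface area: `hr * sv / (1000 * bsa)`.
#'
#' @param hr heart rate, 1/min.
#' @param sv stroke volume, ml.
#' @param bsa body surface area, m^2.
#' @return cardiac index, l/min/m^2.
#' @examples
#' cardiac_index(60, 80, 1.6)  # 3.0
#' @export
cardiac_index <- function(hr, sv, bsa) {
  if (any(!is.finite(hr) | hr <= 0) || any(!is.finite(sv) | sv <= 0) ||
      any(!is.finite(bsa) | bsa <= 0)) {
    stop("hr, sv and bsa must all be positive", call. = FALSE)
  }
  hr * sv / (1000 * bsa)
}

#' Stroke volume index
#'
#' Stroke volume normalized by body surface area.
#'
#' @param sv stroke volume, ml.
#' @param bsa body surface area, m^2.
#' @return stroke volume index, ml/m^2.
#' @examples
#' stroke_volume_index(80, 1.6)  # 50
#' @export
stroke_volume_index <- function(sv, bsa) {
  if (any(!is.finite(sv) | sv <= 0) || any(!is.finite(bsa) | bsa <= 0)) {
    stop("sv and bsa must be positive", call. = FALSE)
  }
  sv / bsa
}
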