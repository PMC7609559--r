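#' Inlet velocity profile
#'
#' A prescribed axial velocity per inlet radial cell, renormalized by one
#' global factor so that the discrete inlet flux (with axisymmetric face
#' weights) equals the measured peak-systolic flow exactly.
#'
#' @param mesh an `axi_mesh`.
#' @param shape axial velocity values (arbitrary scale) at the inlet radial
#'   cell centres, i.e. at radii `eta_c * R` of the inlet face.
#' @param q_mls target inlet flow, ml/s.
#' @param source optional identifier of the source measurement plane.
#' @return An object of class `inlet_profile` with the scaled node
#'   velocities `u` (m/s), the SI flux `q_si`, and the applied
#'   renormalization `factor` (target flux over raw profile flux).
#' @export
inlet_profile <- function(mesh, shape, q_mls, source = NA_character_) {
  stopifnot(inherits(mesh, "axi_mesh"), length(shape) == mesh$nr)
  if (!is.finite(q_mls) || q_mls <= 0) {
    stop("inlet flow must be positive", call. = FALSE)
  }
  deta2 <- diff(mesh$eta_f^2)
  A <- pi * mesh$R_f[1]^2 * deta2
  q_raw <- sum(shape * A)
  if (abs(q_raw) < 1e-15) stop("zero inlet profile flow", call. = FALSE)
  q_si <- q_mls * 1e-6
  factor <- q_si / q_raw
  structure(list(u = shape * factor, q_si = q_si, q_mls = q_mls,
                 factor = factor, source = source),
            class = "inlet_profile")
}

#' Analytic inlet profiles
#'
#' Convenience constructors for solver verification: a parabolic
#' (Poiseuille) or flat (plug) inlet profile carrying a given flow.
#'
#' @param mesh an `axi_mesh`.
#' @param q_mls inlet flow, ml/s.
#' @param kind `"poiseuille"` or `"plug"`.
#' @return An [inlet_profile()].
#' @export
analytic_inlet <- function(mesh, q_mls, kind = c("poiseuille", "plug")) {
  kind <- match.arg(kind)
  shape <- switch(kind,
                  poiseuille = 1 - mesh$eta_c^2,
                  plug = rep(1, mesh$nr))
  inlet_profile(mesh, shape, q_mls, source = kind)
}

#' Map a measured velocity plane onto the mesh inlet
#'
#' Reduces a velocity-encoded measurement plane to the axisymmetric inlet:
#' the through-plane component is azimuthally averaged into a radial
#' profile, linearly interpolated onto the inlet radial nodes (zero outside
#' the measured lumen, consistent with no-slip), and rescaled by one global
#' factor so the discrete inlet flux equals the measured flow. In-plane
#' components have no axisymmetric counterpart at the inlet and are ignored
#' here (they remain available to the plane metrics).
#'
#' @param plane a [velocity_plane()].
#' @param mesh an `axi_mesh`.
#' @param q_mls measured peak-systolic inlet flow, ml/s.
#' @param mismatch_warn relative difference between the plane's own
#'   integrated flow and `q_mls` beyond which a warning is raised
#'   (default 0.25, mirroring a fallback from volumetric to planar
#'   velocimetry).
#' @return An [inlet_profile()].
#' @export
map_inlet_profile <- function(plane, mesh, q_mls, mismatch_warn = 0.25) {
  stopifnot(inherits(plane, "velocity_plane"), inherits(mesh, "axi_mesh"))
  if (!is.finite(q_mls) || q_mls <= 0) {
    stop("measured inlet flow must be positive", call. = FALSE)
  }
  q_plane <- plane_flow(plane)
  if (abs(q_plane) < 1e-12) {
    stop("plane carries no through-plane flow", call. = FALSE)
  }
  rel <- abs(q_plane - q_mls) / q_mls
  if (rel > mismatch_warn) {
    warning(sprintf(paste0(
      "plane flow (%.1f ml/s) and measured flow (%.1f ml/s) differ by ",
      "%.0f%% before renormalization"), q_plane, q_mls, 100 * rel),
      call. = FALSE)
  }
  gx <- outer(plane$x - plane$center[1], rep(1, length(plane$y)))
  gy <- outer(rep(1, length(plane$x)), plane$y - plane$center[2])
  rho <- sqrt(gx^2 + gy^2)[plane$mask] / plane$radius   # normalized radius
  vz <- plane$vz[plane$mask]
  nb <- max(8L, ceiling(plane$radius / min(diff(plane$x))))
  edges <- seq(0, 1, length.out = nb + 1)
  bin <- pmin(findInterval(rho, edges, rightmost.closed = TRUE), nb)
  prof <- tapply(vz, factor(bin, levels = seq_len(nb)), mean)
  mid <- (edges[-1] + edges[-(nb + 1)]) / 2
  ok <- !is.na(prof)
  u_nodes <- approx(x = c(mid[ok], 1), y = c(prof[ok], 0),
                    xout = mesh$eta_c, rule = 2)$y
  inlet_profile(mesh, u_nodes, q_mls, source = plane$id)
}

#' Arch branch tree
#'
#' A small default bifurcation tree for the vessels branching from the
#' aortic arch: the brachiocephalic trunk (splitting into the right
#' subclavian and right common carotid arteries), the left common carotid
#' artery and the left subclavian artery. Radii are typical adult values in
#' metres and can be rescaled.
#'
#' @param scale multiplicative factor on all radii.
#' @return data.frame with columns `id`, `parent` (NA for the arch root),
#'   `radius` (m) and `name`.
#' @export
arch_branch_tree <- function(scale = 1) {
  data.frame(
    id = 1:6,
    parent = c(NA, 1, 1, 1, 2, 2),
    radius = scale * c(0.012, 0.0062, 0.0039, 0.0042, 0.0047, 0.0035),
    name = c("arch", "brachiocephalic", "left_common_carotid",
             "left_subclavian", "right_subclavian", "right_common_carotid"),
    stringsAsFactors = FALSE
  )
}

#' Partition branch flow by Murray's law
#'
#' Distributes a total aortic-arch branch flow over the terminal vessels of
#' a bifurcation tree. At the arch level the default rule assigns half of
#' the total to the brachiocephalic trunk (which supplies two downstream
#' beds, right arm and head) and a quarter each to the left common carotid
#' and left subclavian arteries; the alternative `"equal"` rule splits the
#' arch level into equal thirds. At every subsequent bifurcation, child
#' flows are proportional to the cube of the child radius (Murray's law).
#' Terminal flows sum to the input exactly.
#'
#' @param tree data.frame with columns `id`, `parent` (NA for the single
#'   root whose children are the arch vessels) and `radius` (m); see
#'   [arch_branch_tree()]. The first child of the root is taken to be the
#'   brachiocephalic trunk.
#' @param q_total total branch flow, ml/s (non-negative).
#' @param arch_rule `"brachiocephalic_half"` (default) or `"equal"`.
#' @return data.frame of terminal nodes with their assigned flows (`q`,
#'   ml/s).
#' @export
murray_split <- function(tree, q_total,
                         arch_rule = c("brachiocephalic_half", "equal")) {
  arch_rule <- match.arg(arch_rule)
  stopifnot(is.data.frame(tree), all(c("id", "parent", "radius") %in%
                                       names(tree)))
  if (!is.finite(q_total) || q_total < 0) {
    stop("q_total must be non-negative", call. = FALSE)
  }
  if (any(tree$radius <= 0)) stop("all radii must be > 0", call. = FALSE)
  root <- tree$id[is.na(tree$parent)]
  if (length(root) != 1) stop("tree must have exactly one root", call. = FALSE)
  # acyclicity: walking up from every node must reach the root
  for (id in tree$id) {
    seen <- integer(0); cur <- id
    while (!is.na(cur)) {
      if (cur %in% seen) stop("branch tree contains a cycle", call. = FALSE)
      seen <- c(seen, cur)
      cur <- tree$parent[match(cur, tree$id)]
    }
  }
  q <- setNames(rep(NA_real_, nrow(tree)), tree$id)
  q[as.character(root)] <- q_total
  children_of <- function(id) tree$id[!is.na(tree$parent) & tree$parent == id]
  arch_children <- children_of(root)
  if (length(arch_children)) {
    w <- if (arch_rule == "equal") {
      rep(1 / length(arch_children), length(arch_children))
    } else {
      # first child (brachiocephalic) serves two beds
      wts <- c(2, rep(1, length(arch_children) - 1))
      wts / sum(wts)
    }
    q[as.character(arch_children)] <- q_total * w
  }
  # breadth-first Murray allocation below the arch level
  frontier <- arch_children
  while (length(frontier)) {
    nxt <- integer(0)
    for (id in frontier) {
      ch <- children_of(id)
      if (length(ch)) {
        r3 <- tree$radius[match(ch, tree$id)]^3
        q[as.character(ch)] <- q[as.character(id)] * r3 / sum(r3)
        nxt <- c(nxt, ch)
      }
    }
    frontier <- nxt
  }
  terminal <- tree$id[!tree$id %in% tree$parent]
  out <- tree[match(terminal, tree$id), , drop = FALSE]
  out$q <- as.numeric(q[as.character(terminal)])
  out
}

#' Arch sink band
#'
#' Reduced-order representation of the aortic-arch branch outflow on an
#' axisymmetric vessel: the difference between the ascending and descending
#' peak-systolic flows is extracted through a wall band as a uniform outward
#' normal velocity (flow divided by the band's lateral area
#' \eqn{\int 2\pi r \sqrt{1 + r'^2}\, dz}).
#'
#' @param geometry a `vessel_geometry` (its `branch_band` is used).
#' @param q_asc,q_desc peak-systolic ascending and descending flows, ml/s
#'   with `q_asc >= q_desc >= 0`.
#' @return An object of class `sink_band` with the band, the uniform normal
#'   velocity `v_n` (m/s), the band lateral `area` (m^2) and the extracted
#'   flux (`q_mls`, `q_si`).
#' @export
build_sink_band <- function(geometry, q_asc, q_desc) {
  stopifnot(inherits(geometry, "vessel_geometry"))
  if (q_desc < 0) stop("q_desc must be >= 0", call. = FALSE)
  if (q_asc < q_desc) {
    stop("descending flow exceeds ascending flow; the band cannot extract ",
         "a negative flux (possible collateral flow)", call. = FALSE)
  }
  band <- geometry$branch_band
  area <- stats::integrate(function(z) {
    2 * pi * vessel_radius(geometry, z) *
      sqrt(1 + vessel_radius(geometry, z, deriv = TRUE)^2)
  }, band[1], band[2], rel.tol = 1e-10)$value
  q_si <- (q_asc - q_desc) * 1e-6
  structure(list(band = band, v_n = q_si / area, area = area,
                 q_mls = q_asc - q_desc, q_si = q_si),
            class = "sink_band")
}
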