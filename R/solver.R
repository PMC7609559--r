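#' Solver controls
#'
#' Controls for the SIMPLE pressure-velocity iteration: blood density,
#' under-relaxation factors for momentum, pressure and viscosity, the
#' normalized-residual convergence tolerance and the iteration cap. The
#' solver is deterministic.
#'
#' @param density blood density, kg/m^3 (default 1050).
#' @param alpha_u momentum under-relaxation factor.
#' @param alpha_p pressure under-relaxation factor.
#' @param alpha_mu viscosity under-relaxation factor.
#' @param tol convergence tolerance on all normalized residuals.
#' @param max_iter maximum number of SIMPLE iterations.
#' @param divergence_factor residual growth (relative to the best residual
#'   so far) that is treated as divergence.
#' @return An object of class `solver_params`.
#' @export
solver_params <- function(density = 1050, alpha_u = 0.7, alpha_p = 0.3,
                          alpha_mu = 0.5, tol = 1e-6, max_iter = 20000,
                          divergence_factor = 1e6) {
  stopifnot(density > 0, alpha_u > 0, alpha_u <= 1, alpha_p > 0,
            alpha_p <= 1, tol > 0, max_iter >= 1)
  structure(list(density = density, alpha_u = alpha_u, alpha_p = alpha_p,
                 alpha_mu = alpha_mu, tol = tol, max_iter = max_iter,
                 divergence_factor = divergence_factor),
            class = "solver_params")
}

# shear-rate magnitude sqrt(2 D:D) at cell centres, including the
# axisymmetric hoop term u_r / r
shear_rate_cc <- function(mesh, u, v) {
  nz <- mesh$nz; nr <- mesh$nr
  u_cc <- 0.5 * (u[-1, , drop = FALSE] + u[-(nz + 1), , drop = FALSE])
  v_cc <- 0.5 * (v[, -1, drop = FALSE] + v[, -(nr + 1), drop = FALSE])
  r_cc <- outer(mesh$R_c, mesh$eta_c)
  dudz <- (u[-1, , drop = FALSE] - u[-(nz + 1), , drop = FALSE]) / mesh$dz
  dvdr <- (v[, -1, drop = FALSE] - v[, -(nr + 1), drop = FALSE]) /
    outer(mesh$R_c, mesh$deta)
  # radial gradient of u at centres: central differences on eta_c * R
  dudr <- matrix(0, nz, nr)
  if (nr >= 2) {
    for (j in seq_len(nr)) {
      jm <- max(j - 1L, 1L); jp <- min(j + 1L, nr)
      dudr[, j] <- (u_cc[, jp] - u_cc[, jm]) /
        ((mesh$eta_c[jp] - mesh$eta_c[jm]) * mesh$R_c)
    }
  }
  dvdz <- matrix(0, nz, nr)
  if (nz >= 2) {
    for (i in seq_len(nz)) {
      im <- max(i - 1L, 1L); ip <- min(i + 1L, nz)
      dvdz[i, ] <- (v_cc[ip, ] - v_cc[im, ]) / (mesh$z_c[ip] - mesh$z_c[im])
    }
  }
  hoop <- ifelse(r_cc > 0, v_cc / r_cc, 0)
  sqrt(2 * (dudz^2 + dvdr^2 + hoop^2) + (dudr + dvdz)^2)
}

#' Solve steady laminar axisymmetric flow
#'
#' Steady, incompressible, laminar Navier-Stokes on the mapped axisymmetric
#' grid of [generate_mesh()], with SIMPLE pressure-velocity coupling on a
#' staggered arrangement, first-order upwind convection, deformation-rate
#' dependent viscosity, a prescribed inlet velocity profile, no-slip rigid
#' walls, an optional uniform wall sink band extracting the aortic-arch
#' branch flow, axis symmetry, and a zero-gradient outlet whose flux is
#' constrained to the global mass balance. Face mass fluxes are formed in
#' physical space (including the wall-slope projection on the mapped radial
#' faces), so converged fields satisfy discrete continuity cell by cell.
#'
#' @param mesh an `axi_mesh`.
#' @param bcs boundary conditions: a list with elements `inlet` (an
#'   [inlet_profile()]) and optionally `sink` (a [build_sink_band()] result).
#' @param rheology a [carreau_yasuda()] or [newtonian()] model.
#' @param params a [solver_params()].
#' @return An object of class `flow_field`: axial velocity `u` (on axial
#'   faces), radial velocity `v` (on radial faces), cell pressures `p` (Pa,
#'   gauge, outlet-referenced), effective viscosity `mu`, wall shear profile
#'   `wall_tau` (Pa), residual history, iteration count, convergence flag and
#'   the inlet Reynolds number.
#' @export
solve_steady_flow <- function(mesh, bcs, rheology = carreau_yasuda(),
                              params = solver_params()) {
  stopifnot(inherits(mesh, "axi_mesh"), is.list(bcs),
            inherits(bcs$inlet, "inlet_profile"),
            inherits(rheology, "rheology"), inherits(params, "solver_params"))
  nz <- mesh$nz; nr <- mesh$nr
  rho <- params$density
  dz <- mesh$dz; z_c <- mesh$z_c; z_f <- mesh$z_f
  eta_c <- mesh$eta_c; eta_f <- mesh$eta_f
  deta <- mesh$deta; deta2 <- diff(eta_f^2)
  R_c <- mesh$R_c; R_f <- mesh$R_f

  u_in <- bcs$inlet$u                       # inlet axial velocity per cell j
  q_in <- bcs$inlet$q_si                    # m^3/s
  A_f <- outer(pi * R_f^2, deta2)           # (nz+1) x nr axial face areas
  # wall sink velocity per axial cell
  v_wall <- rep(0, nz)
  if (!is.null(bcs$sink)) {
    stopifnot(inherits(bcs$sink, "sink_band"))
    band <- bcs$sink$band
    in_band <- z_c >= band[1] & z_c <= band[2]
    if (!any(in_band) && bcs$sink$q_si > 0) {
      stop("sink band does not overlap any mesh cell", call. = FALSE)
    }
    if (any(in_band)) {
      a_band <- sum(2 * pi * R_c[in_band] * dz[in_band])
      v_wall[in_band] <- bcs$sink$q_si / a_band   # exact discrete extraction
    }
  }
  q_sink <- sum(v_wall * 2 * pi * R_c * dz)
  q_out <- q_in - q_sink
  if (q_out < -1e-12) {
    stop("sink extracts more than the inlet supplies", call. = FALSE)
  }

  zero_field <- function() {
    fld <- structure(
      list(mesh = mesh, u = matrix(0, nz + 1, nr), v = matrix(0, nz, nr + 1),
           p = matrix(0, nz, nr), mu = matrix(viscosity_of(rheology, 0), nz, nr),
           wall_tau = rep(0, nz), residuals = numeric(0), iterations = 0L,
           converged = TRUE, reynolds = 0, rheology = rheology,
           params = params, q_in = 0, q_out = 0, v_wall = v_wall),
      class = "flow_field")
    fld
  }
  if (abs(q_in) < 1e-15 && q_sink < 1e-15) return(zero_field())
  if (q_in <= 0) stop("inlet flow must be positive", call. = FALSE)

  u_ref <- q_in / (pi * R_f[1]^2)
  mom_scale <- rho * q_in * u_ref

  # initial guess: mass-consistent plug flow
  q_cum <- q_in - c(0, cumsum(v_wall * 2 * pi * R_c * dz))  # at z-faces
  u <- matrix(q_cum / (pi * R_f^2), nz + 1, nr)
  u[, nr] <- u[, nr] * 0.5                 # soften towards no-slip
  u[1, ] <- u_in
  v <- matrix(0, nz, nr + 1)
  v[, nr + 1] <- v_wall
  p <- matrix(0, nz, nr)
  mu <- matrix(viscosity_of(rheology, 100), nz, nr)

  iu <- function(k, j) (k - 2L) * nr + j        # u unknowns k = 2..nz
  iv <- function(i, m) (i - 1L) * (nr - 1L) + (m - 1L)  # v unknowns m = 2..nr
  ip <- function(i, j) (i - 1L) * nr + j
  n_u <- (nz - 1L) * nr
  n_v <- nz * (nr - 1L)
  n_p <- nz * nr

  hist <- numeric(0)
  converged <- FALSE
  best_res <- Inf

  # enumeration order matches the row-index maps (j/m fastest), so the
  # right-hand sides and solution vectors need no permutation
  Kj <- cbind(k = rep(2:nz, each = nr), j = rep(seq_len(nr), nz - 1L))
  Im <- cbind(i = rep(seq_len(nz), each = nr - 1L),
              m = rep(2:nr, nz))

  for (iter in seq_len(params$max_iter)) {
    # ---- face fluxes ----
    Fm <- u * A_f                                       # (nz+1) x nr
    u_cc <- 0.5 * (u[-1, , drop = FALSE] + u[-(nz + 1), , drop = FALSE])
    u_ef <- cbind(u_cc[, 1],
                  0.5 * (u_cc[, -nr, drop = FALSE] + u_cc[, -1, drop = FALSE]),
                  rep(0, nz))                           # nz x (nr+1)
    A_v <- 2 * pi * outer(R_c * dz, eta_f)              # nz x (nr+1)
    slope <- outer(mesh$dRdz_c, eta_f)
    G <- (v - u_ef * slope) * A_v
    G[, 1] <- 0

    # ---- u momentum (k = 2..nz) ----
    k <- Kj[, 1]; j <- Kj[, 2]
    Fe <- 0.5 * (Fm[cbind(k, j)] + Fm[cbind(k + 1, j)])
    Fw <- 0.5 * (Fm[cbind(k - 1, j)] + Fm[cbind(k, j)])
    Gn <- 0.5 * (G[cbind(k - 1, j + 1)] + G[cbind(k, j + 1)])
    Gs <- 0.5 * (G[cbind(k - 1, j)] + G[cbind(k, j)])

    De <- mu[cbind(k, j)] * pi * R_c[k]^2 * deta2[j] / dz[k]
    Dw <- mu[cbind(k - 1, j)] * pi * R_c[k - 1]^2 * deta2[j] / dz[k - 1]
    dzu <- 0.5 * (dz[k - 1] + dz[k])
    # north (towards wall)
    dist_n <- ifelse(j < nr, (eta_c[pmin(j + 1, nr)] - eta_c[j]) * R_f[k],
                     (1 - eta_c[nr]) * R_f[k])
    mu_n <- ifelse(j < nr,
                   0.25 * (mu[cbind(k - 1, j)] + mu[cbind(k, j)] +
                           mu[cbind(k - 1, pmin(j + 1, nr))] +
                           mu[cbind(k, pmin(j + 1, nr))]),
                   0.5 * (mu[cbind(k - 1, j)] + mu[cbind(k, j)]))
    Dn <- mu_n * 2 * pi * eta_f[j + 1] * R_f[k] * dzu / dist_n
    dist_s <- ifelse(j > 1, (eta_c[j] - eta_c[pmax(j - 1, 1)]) * R_f[k], 1)
    mu_s <- 0.25 * (mu[cbind(k - 1, j)] + mu[cbind(k, j)] +
                    mu[cbind(k - 1, pmax(j - 1, 1))] +
                    mu[cbind(k, pmax(j - 1, 1))])
    Ds <- ifelse(j > 1, mu_s * 2 * pi * eta_f[j] * R_f[k] * dzu / dist_s, 0)

    aE <- De + pmax(-rho * Fe, 0)
    aW <- Dw + pmax(rho * Fw, 0)
    aN <- Dn + pmax(-rho * Gn, 0)
    aS <- Ds + pmax(rho * Gs, 0)
    aP <- aE + aW + aN + aS + rho * (Fe - Fw + Gn - Gs)
    b <- (p[cbind(k - 1, j)] - p[cbind(k, j)]) * A_f[cbind(k, j)]
    # Dirichlet / explicit neighbours into rhs
    b <- b + ifelse(k == 2, aW * u[cbind(rep(1L, length(k)), j)], 0)
    b <- b + ifelse(k == nz, aE * u[cbind(rep(nz + 1L, length(k)), j)], 0)
    # wall Dirichlet u = 0 at j = nr contributes nothing to rhs
    aP_r <- aP / params$alpha_u
    b_r <- b + (1 - params$alpha_u) / params$alpha_u * aP * u[cbind(k, j)]

    rows <- iu(k, j); cols_self <- rows
    use_w <- k > 2; use_e <- k < nz; use_s <- j > 1; use_n <- j < nr
    tri_i <- c(rows, rows[use_w], rows[use_e], rows[use_s], rows[use_n])
    tri_j <- c(cols_self, iu(k[use_w] - 1L, j[use_w]),
               iu(k[use_e] + 1L, j[use_e]),
               iu(k[use_s], j[use_s] - 1L), iu(k[use_n], j[use_n] + 1L))
    tri_x <- c(aP_r, -aW[use_w], -aE[use_e], -aS[use_s], -aN[use_n])
    Au <- Matrix::sparseMatrix(i = tri_i, j = tri_j, x = tri_x,
                               dims = c(n_u, n_u))
    u_old_vec <- u[cbind(k, j)]
    res_u <- sum(abs(b + ifelse(use_w, aW * u[cbind(pmax(k - 1, 1), j)], 0) +
                       ifelse(use_e, aE * u[cbind(pmin(k + 1, nz + 1), j)], 0) +
                       ifelse(use_s, aS * u[cbind(k, pmax(j - 1, 1))], 0) +
                       ifelse(use_n, aN * u[cbind(k, pmin(j + 1, nr))], 0) -
                       aP * u_old_vec)) / mom_scale
    u_new <- as.numeric(Matrix::solve(Au, b_r))
    u[cbind(k, j)] <- u_new
    dU <- A_f[cbind(k, j)] / aP_r
    d_u <- matrix(0, nz + 1, nr); d_u[cbind(k, j)] <- dU

    # outlet: zero-gradient copy scaled to the global mass balance
    q_copy <- sum(u[nz, ] * A_f[nz + 1, ])
    u[nz + 1, ] <- if (q_copy > 0) u[nz, ] * (q_out / q_copy) else
      q_out / (pi * R_f[nz + 1]^2)

    # ---- v momentum (m = 2..nr) ----
    i <- Im[, 1]; m <- Im[, 2]
    Fm2 <- u * A_f
    Fe <- 0.5 * (Fm2[cbind(i + 1, m - 1)] + Fm2[cbind(i + 1, m)])
    Fw <- 0.5 * (Fm2[cbind(i, m - 1)] + Fm2[cbind(i, m)])
    u_cc <- 0.5 * (u[-1, , drop = FALSE] + u[-(nz + 1), , drop = FALSE])
    u_ef <- cbind(u_cc[, 1],
                  0.5 * (u_cc[, -nr, drop = FALSE] + u_cc[, -1, drop = FALSE]),
                  rep(0, nz))
    G2 <- (v - u_ef * slope) * A_v
    G2[, 1] <- 0
    Gn <- 0.5 * (G2[cbind(i, m)] + G2[cbind(i, pmin(m + 1, nr + 1))])
    Gs <- 0.5 * (G2[cbind(i, m - 1)] + G2[cbind(i, m)])

    deta_cv <- eta_c[m] - eta_c[m - 1]
    mu_e <- 0.25 * (mu[cbind(i, m - 1)] + mu[cbind(i, m)] +
                    mu[cbind(pmin(i + 1, nz), m - 1)] +
                    mu[cbind(pmin(i + 1, nz), m)])
    Ae_v <- pi * R_f[i + 1]^2 * (eta_c[m]^2 - eta_c[m - 1]^2)
    De <- ifelse(i < nz, mu_e * Ae_v / (z_c[pmin(i + 1, nz)] - z_c[i]), 0)
    mu_w <- 0.25 * (mu[cbind(i, m - 1)] + mu[cbind(i, m)] +
                    mu[cbind(pmax(i - 1, 1), m - 1)] +
                    mu[cbind(pmax(i - 1, 1), m)])
    Aw_v <- pi * R_f[i]^2 * (eta_c[m]^2 - eta_c[m - 1]^2)
    Dw <- ifelse(i > 1, mu_w * Aw_v / (z_c[i] - z_c[pmax(i - 1, 1)]),
                 mu_w * Aw_v / (z_c[1] - z_f[1]))
    Dn <- mu[cbind(i, m)] * 2 * pi * eta_c[m] * R_c[i] * dz[i] /
      (deta[m] * R_c[i])
    Ds <- mu[cbind(i, m - 1)] * 2 * pi * eta_c[m - 1] * R_c[i] * dz[i] /
      (deta[m - 1] * R_c[i])

    aE <- De + pmax(-rho * Fe, 0)
    aW <- Dw + pmax(rho * Fw, 0)
    aN <- Dn + pmax(-rho * Gn, 0)
    aS <- Ds + pmax(rho * Gs, 0)
    r_v <- eta_f[m] * R_c[i]
    vol_v <- 2 * pi * r_v * deta_cv * R_c[i] * dz[i]
    s_hoop <- 0.5 * (mu[cbind(i, m - 1)] + mu[cbind(i, m)]) * vol_v / r_v^2
    aP <- aE + aW + aN + aS + rho * (Fe - Fw + Gn - Gs) + s_hoop
    A_lat <- 2 * pi * eta_f[m] * R_c[i] * dz[i]
    b <- (p[cbind(i, m - 1)] - p[cbind(i, m)]) * A_lat
    b <- b + ifelse(m == nr, aN * v_wall[i], 0)
    aP_r_v <- aP / params$alpha_u
    b_r <- b + (1 - params$alpha_u) / params$alpha_u * aP * v[cbind(i, m)]

    rows <- iv(i, m)
    use_w <- i > 1; use_e <- i < nz; use_s <- m > 2; use_n <- m < nr
    tri_i <- c(rows, rows[use_w], rows[use_e], rows[use_s], rows[use_n])
    tri_j <- c(rows, iv(i[use_w] - 1L, m[use_w]), iv(i[use_e] + 1L, m[use_e]),
               iv(i[use_s], m[use_s] - 1L), iv(i[use_n], m[use_n] + 1L))
    tri_x <- c(aP_r_v, -aW[use_w], -aE[use_e], -aS[use_s], -aN[use_n])
    Av <- Matrix::sparseMatrix(i = tri_i, j = tri_j, x = tri_x,
                               dims = c(n_v, n_v))
    v_old_vec <- v[cbind(i, m)]
    res_v <- sum(abs(b + ifelse(use_w, aW * v[cbind(pmax(i - 1, 1), m)], 0) +
                       ifelse(use_e, aE * v[cbind(pmin(i + 1, nz), m)], 0) +
                       ifelse(use_s, aS * v[cbind(i, pmax(m - 1, 2))], 0) +
                       ifelse(use_n, aN * v[cbind(i, pmin(m + 1, nr))], 0) -
                       aP * v_old_vec)) / mom_scale
    v_new <- as.numeric(Matrix::solve(Av, b_r))
    v[cbind(i, m)] <- v_new
    d_v <- matrix(0, nz, nr + 1)
    d_v[cbind(i, m)] <- A_lat / aP_r_v

    # ---- pressure correction ----
    Fm3 <- u * A_f
    u_cc <- 0.5 * (u[-1, , drop = FALSE] + u[-(nz + 1), , drop = FALSE])
    u_ef <- cbind(u_cc[, 1],
                  0.5 * (u_cc[, -nr, drop = FALSE] + u_cc[, -1, drop = FALSE]),
                  rep(0, nz))
    G3 <- (v - u_ef * slope) * A_v
    G3[, 1] <- 0
    imb <- (Fm3[-1, , drop = FALSE] - Fm3[-(nz + 1), , drop = FALSE]) +
      (G3[, -1, drop = FALSE] - G3[, -(nr + 1), drop = FALSE])
    res_c <- sum(abs(imb)) / q_in

    ii <- rep(seq_len(nz), each = nr); jj <- rep(seq_len(nr), nz)
    aEp <- ifelse(ii < nz, A_f[cbind(ii + 1, jj)] *
                    d_u[cbind(pmin(ii + 1, nz + 1), jj)], 0)
    aWp <- ifelse(ii > 1, A_f[cbind(ii, jj)] * d_u[cbind(ii, jj)], 0)
    aNp <- ifelse(jj < nr, A_v[cbind(ii, jj + 1)] *
                    d_v[cbind(ii, pmin(jj + 1, nr + 1))], 0)
    aSp <- ifelse(jj > 1, A_v[cbind(ii, jj)] * d_v[cbind(ii, jj)], 0)
    aPp <- aEp + aWp + aNp + aSp
    bp <- -imb[cbind(ii, jj)]
    rows <- ip(ii, jj)
    pin <- ip(nz, 1L)
    keep <- rows != pin
    use_w <- ii > 1 & keep; use_e <- ii < nz & keep
    use_s <- jj > 1 & keep; use_n <- jj < nr & keep
    tri_i <- c(rows[keep], rows[use_w], rows[use_e], rows[use_s], rows[use_n],
               pin)
    tri_j <- c(rows[keep], ip(ii[use_w] - 1L, jj[use_w]),
               ip(ii[use_e] + 1L, jj[use_e]), ip(ii[use_s], jj[use_s] - 1L),
               ip(ii[use_n], jj[use_n] + 1L), pin)
    tri_x <- c(aPp[keep], -aWp[use_w], -aEp[use_e], -aSp[use_s], -aNp[use_n],
               1)
    bp[rows == pin] <- 0
    Ap <- Matrix::sparseMatrix(i = tri_i, j = tri_j, x = tri_x,
                               dims = c(n_p, n_p))
    # rows are already the identity permutation (j fastest); reshape to
    # (i, j) with j along columns
    pc <- t(matrix(as.numeric(Matrix::solve(Ap, bp)), nr, nz))

    # corrections
    kk <- Kj[, 1]; jj2 <- Kj[, 2]
    u[cbind(kk, jj2)] <- u[cbind(kk, jj2)] +
      d_u[cbind(kk, jj2)] * (pc[cbind(kk - 1, jj2)] - pc[cbind(kk, jj2)])
    iiv <- Im[, 1]; mmv <- Im[, 2]
    v[cbind(iiv, mmv)] <- v[cbind(iiv, mmv)] +
      d_v[cbind(iiv, mmv)] * (pc[cbind(iiv, mmv - 1)] - pc[cbind(iiv, mmv)])
    p <- p + params$alpha_p * pc

    # viscosity update
    gam <- shear_rate_cc(mesh, u, v)
    mu_new <- matrix(viscosity_of(rheology, as.numeric(gam)), nz, nr)
    mu <- mu + params$alpha_mu * (mu_new - mu)

    res <- max(res_u, res_v, res_c)
    if (isTRUE(getOption("coarctflow.debug"))) {
      cat(sprintf("it %d ru %.3g rv %.3g rc %.3g |u| %.3g |v| %.3g |p| %.3g\n",
                  iter, res_u, res_v, res_c, max(abs(u)), max(abs(v)),
                  max(abs(p))))
    }
    hist <- c(hist, res)
    if (!is.finite(res)) {
      stop(structure(class = c("solver_divergence", "error", "condition"),
                     list(message = "solver diverged (non-finite residuals)",
                          call = sys.call(-1), residuals = hist)))
    }
    best_res <- min(best_res, res)
    if (res > params$divergence_factor * best_res && iter > 20) {
      stop(structure(class = c("solver_divergence", "error", "condition"),
                     list(message = sprintf(
                       "solver diverged: residual %.3g after %d iterations",
                       res, iter), call = sys.call(-1), residuals = hist)))
    }
    if (res < params$tol && iter > 2) {
      converged <- TRUE
      break
    }
  }

  field <- structure(
    list(mesh = mesh, u = u, v = v, p = p, mu = mu, wall_tau = NULL,
         residuals = hist, iterations = length(hist), converged = converged,
         reynolds = 2 * rho * q_in / (pi * R_f[1] *
                      viscosity_of(rheology, 8 * u_ref / (2 * R_f[1]))),
         rheology = rheology, params = params,
         q_in = q_in, q_out = q_out, v_wall = v_wall),
    class = "flow_field")
  # outlet-referenced gauge pressure
  pbar_out <- sum(field$p[nz, ] * deta2) / sum(deta2)
  field$p <- field$p - pbar_out
  if (converged) field$wall_tau <- wall_shear(field)
  field
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf(
    "<flow_field> %d x %d cells, %s after %d iterations (residual %.2e), Re %.0f\n",
    x$mesh$nz, x$mesh$nr,
    if (x$converged) "converged" else "NOT converged",
    x$iterations,
    if (length(x$residuals)) x$residuals[length(x$residuals)] else 0,
    x$reynolds))
  invisible(x)
}

#' Wall shear stress profile
#'
#' Wall shear \eqn{\tau_w = \mu(\dot\gamma_w)\,|\partial u_t/\partial n|}
#' along the wall, with the wall-normal velocity gradient evaluated by
#' one-sided second-order differencing through the graded wall layers (a
#' quadratic through the wall no-slip point and the two nearest cell-centre
#' velocities).
#'
#' @param field a converged `flow_field`.
#' @return numeric vector of wall shear stresses (Pa, non-negative), one per
#'   axial cell.
#' @export
wall_shear <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  if (!field$converged) {
    stop("wall shear requires a converged flow field", call. = FALSE)
  }
  mesh <- field$mesh
  nz <- mesh$nz; nr <- mesh$nr
  u_cc <- 0.5 * (field$u[-1, , drop = FALSE] +
                 field$u[-(nz + 1), , drop = FALSE])
  d1 <- (1 - mesh$eta_c[nr]) * mesh$R_c
  d2 <- (1 - mesh$eta_c[nr - 1]) * mesh$R_c
  u1 <- u_cc[, nr]; u2 <- u_cc[, nr - 1]
  dudn <- abs((d2^2 * u1 - d1^2 * u2) / (d1 * d2 * (d2 - d1)))
  # wall-parallel correction for sloped walls is second order in dR/dz
  mu_w <- viscosity_of(field$rheology, dudn)
  as.numeric(mu_w * dudn)
}

#' Through-plane volumetric flux profile
#'
#' Net volumetric flux through every axial grid plane (m^3/s converted to
#' ml/s), for mass-conservation checks: in a converged field the flux at a
#' plane equals the inlet flow minus the sink extraction upstream of it.
#'
#' @param field a `flow_field`.
#' @return data.frame with columns `z` (m), `q` (ml/s) and `q_expected`
#'   (ml/s).
#' @export
flux_profile <- function(field) {
  mesh <- field$mesh
  deta2 <- diff(mesh$eta_f^2)
  A_f <- outer(pi * mesh$R_f^2, deta2)
  q <- rowSums(field$u * A_f)
  q_sink_cum <- c(0, cumsum(field$v_wall * 2 * pi * mesh$R_c * mesh$dz))
  data.frame(z = mesh$z_f, q = q / 1e-6,
             q_expected = (field$q_in - q_sink_cum) / 1e-6)
}
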