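# shared fixtures and independent oracles for the test suite

# memoized coarse straight-tube Newtonian solve (R = 10 mm, Q in ml/s)
.solve_cache <- new.env(parent = emptyenv())
poiseuille_field <- function(q = 100, delta = 1e-3, L = 0.02,
                             rheology = newtonian(3.5e-3)) {
  key <- paste(q, delta, L, class(rheology)[1], sep = "|")
  if (is.null(.solve_cache[[key]])) {
    v <- build_vessel(r_ref = 0.01, d = 0, length = L, l_s = L / 5,
                      z_s = L / 2, branch_band = c(0.6 * L, 0.8 * L))
    m <- generate_mesh(v, mesh_spec(delta = delta))
    f <- solve_steady_flow(m, list(inlet = analytic_inlet(m, q)),
                           rheology = rheology)
    .solve_cache[[key]] <- f
  }
  .solve_cache[[key]]
}

# build a velocity plane directly from velocity functions of (x, y)
plane_from_fun <- function(fz, fx = function(x, y) 0 * x,
                           fy = function(x, y) 0 * x,
                           radius = 0.01, n = 64) {
  half <- radius * (1 + 1 / n)
  x <- seq(-half, half, length.out = n)
  gx <- outer(x, rep(1, n)); gy <- outer(rep(1, n), x)
  mask <- gx^2 + gy^2 <= radius^2
  vz <- matrix(fz(gx, gy), n, n)
  vx <- matrix(fx(gx, gy), n, n)
  vy <- matrix(fy(gx, gy), n, n)
  vz[!mask] <- 0; vx[!mask] <- 0; vy[!mask] <- 0
  velocity_plane(x, x, vx, vy, vz, mask, center = c(0, 0), radius = radius)
}

# analytic mean of a normal truncated to (lo, hi)
truncnorm_mean <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd; b <- (hi - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# brute-force two-sided signed-rank p-value by enumerating all sign
# assignments of the ranked absolute differences
signed_rank_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  t_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  t_all <- as.numeric(signs %*% rk)
  p_lo <- mean(t_all <= t_obs)
  p_hi <- mean(t_all >= t_obs)
  min(1, 2 * min(p_lo, p_hi))
}
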