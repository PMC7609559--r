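test_that("Carreau-Yasuda limits and closed form are reproduced", {
  cy <- carreau_yasuda()
  expect_equal(carreau_yasuda_viscosity(0, cy), 0.16)
  expect_lt(abs(carreau_yasuda_viscosity(1e6, cy) - 0.0035) / 0.0035, 0.01)
  # independently evaluated closed form at 100 1/s
  expect_equal(carreau_yasuda_viscosity(100, cy), 4.2825595e-3,
               tolerance = 1e-6)
  expect_error(carreau_yasuda_viscosity(-1, cy), ">= 0")
  expect_error(carreau_yasuda(mu0 = 0.001), "mu0")
})

test_that("viscosity is monotone non-increasing and bounded", {
  cy <- carreau_yasuda()
  gam <- 10^seq(-3, 6, length.out = 200)
  mu <- carreau_yasuda_viscosity(gam, cy)
  expect_true(all(diff(mu) <= 0))
  expect_true(all(mu <= cy$mu0 & mu >= cy$mu_inf))
})

test_that("the straight-tube solution matches Hagen-Poiseuille", {
  f <- poiseuille_field(q = 100, delta = 1e-3)
  expect_true(f$converged)
  m <- f$mesh
  Q <- 1e-4; R <- 0.01; mu <- 3.5e-3
  i <- round(m$nz / 2)
  ucc <- 0.5 * (f$u[i, ] + f$u[i + 1, ])
  ua <- 2 * Q / (pi * R^2) * (1 - m$eta_c^2)
  expect_lt(max(abs(ucc - ua)) / max(ua), 0.02)
  # wall shear 4 mu Q / (pi R^3) = 0.4456 Pa
  expect_equal(mean(f$wall_tau), 0.4456338, tolerance = 0.02)
  # axial pressure drop 8 mu Q / (pi R^4), coarse-mesh tolerance
  deta2 <- diff(m$eta_f^2)
  pbar <- as.numeric(f$p %*% deta2) / sum(deta2)
  dpdz <- (pbar[2] - pbar[m$nz - 1]) / (m$z_c[m$nz - 1] - m$z_c[2])
  expect_equal(dpdz, 8 * mu * Q / (pi * R^4), tolerance = 0.06)
  # discrete continuity to solver tolerance in every transverse plane
  fp <- flux_profile(f)
  expect_lt(max(abs(fp$q - fp$q_expected)) / 100, 1e-6)
})

test_that("wall shear is linear in flow for the Newtonian straight tube", {
  f1 <- poiseuille_field(q = 50, delta = 1e-3)
  f2 <- poiseuille_field(q = 100, delta = 1e-3)
  expect_equal(mean(f2$wall_tau) / mean(f1$wall_tau), 2, tolerance = 0.01)
})

test_that("zero inflow gives the rest state", {
  v <- build_vessel(r_ref = 0.01, d = 0.2, length = 0.02, l_s = 0.005,
                    z_s = 0.01, branch_band = c(0.012, 0.016))
  m <- generate_mesh(v, mesh_spec(delta = 1e-3))
  shape <- rep(1, m$nr)
  inl <- structure(list(u = shape * 0, q_si = 0, q_mls = 0, factor = 0,
                        source = "zero"), class = "inlet_profile")
  f <- solve_steady_flow(m, list(inlet = inl))
  expect_true(f$converged)
  expect_equal(max(abs(f$u)), 0)
  expect_equal(max(abs(f$p) - min(f$p)), 0)
  expect_equal(wall_shear(f), rep(0, m$nz))
})

test_that("effective viscosity respects the rheological bounds", {
  v <- build_vessel(r_ref = 0.008, d = 0.4, length = 0.05, l_s = 0.01,
                    z_s = 0.03, branch_band = c(0.012, 0.02))
  m <- generate_mesh(v, mesh_spec(delta = 1e-3))
  cy <- carreau_yasuda()
  f <- solve_steady_flow(m, list(inlet = analytic_inlet(m, 25)),
                         rheology = cy)
  expect_true(f$converged)
  expect_true(all(f$mu <= cy$mu0 + 1e-12))
  expect_true(all(f$mu >= cy$mu_inf - 1e-12))
  # shear-thinning: higher flow lowers the viscosity everywhere it shears
  f2 <- solve_steady_flow(m, list(inlet = analytic_inlet(m, 50)),
                          rheology = cy)
  expect_lt(mean(f2$mu), mean(f$mu))
})

test_that("non-converged fields refuse to yield wall shear or gradients", {
  v <- build_vessel(r_ref = 0.01, d = 0, length = 0.02, l_s = 0.004,
                    z_s = 0.01, branch_band = c(0.012, 0.016))
  m <- generate_mesh(v, mesh_spec(delta = 1e-3))
  f <- solve_steady_flow(m, list(inlet = analytic_inlet(m, 100)),
                         rheology = newtonian(),
                         params = solver_params(max_iter = 3))
  expect_false(f$converged)
  expect_error(wall_shear(f), "converged")
  expect_error(pressure_gradient(f), "converged")
})

test_that("flow-field VTK export is well formed", {
  f <- poiseuille_field(q = 100, delta = 1e-3)
  path <- withr::local_tempfile(fileext = ".vtk")
  write_vtk_field(f, path)
  lines <- readLines(path)
  expect_identical(lines[1], "# vtk DataFile Version 3.0")
  expect_match(lines[5], sprintf("DIMENSIONS %d %d 1", f$mesh$nz, f$mesh$nr))
  n_pts <- f$mesh$nz * f$mesh$nr
  expect_match(lines[6], sprintf("POINTS %d double", n_pts))
  expect_identical(sum(lines == "LOOKUP_TABLE default"), 2L)
})
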