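test_that("inlet mapping renormalizes to the measured flow exactly", {
  v <- build_vessel(r_ref = 0.012, d = 0.3)
  m <- generate_mesh(v, mesh_spec(delta = 1e-3))
  deta2 <- diff(m$eta_f^2)
  flux <- function(ip) sum(ip$u * pi * m$R_f[1]^2 * deta2) / 1e-6

  pl <- synthesize_plane(0.012, 400, profile = list(k = 2, d = 0, s = 0))
  ip <- map_inlet_profile(pl, m, 400)
  expect_equal(ip$factor, 1, tolerance = 0.005)     # consistent plane
  expect_equal(flux(ip), 400, tolerance = 1e-9)

  # doubling the plane velocities halves the renormalization factor
  pl2 <- pl; pl2$vz <- 2 * pl$vz
  ip2 <- suppressWarnings(map_inlet_profile(pl2, m, 400))
  expect_equal(ip2$factor / ip$factor, 0.5, tolerance = 1e-12)

  # noisy plane still hits the measured flow exactly after scaling
  pln <- synthesize_plane(0.012, 400, profile = list(k = 3, d = 0.2, s = 0),
                          noise_sd = 0.05, seed = 4)
  ipn <- map_inlet_profile(pln, m, 400)
  expect_equal(flux(ipn), 400, tolerance = 1e-9)

  expect_warning(map_inlet_profile(pl, m, 600), "differ")
  zero <- pl; zero$vz[] <- 0
  expect_error(map_inlet_profile(zero, m, 400), "no through-plane flow")
  expect_error(analytic_inlet(m, -5), "positive")
})

test_that("Murray split follows the radius-cubed rule below the arch", {
  # a single arch vessel feeding one bifurcation isolates the r^3 rule
  tr <- data.frame(id = 1:4, parent = c(NA, 1, 2, 2), radius = c(1, 1, 2, 1))
  out <- murray_split(tr, 90)
  q <- setNames(out$q, out$id)
  expect_equal(as.numeric(q["3"] / q["4"]), 8)      # radii 2 : 1 -> 8 : 1
  expect_identical(sum(out$q), 90)                   # exact, not approximate
  # equal radii split evenly
  tr$radius <- c(1, 1, 1.5, 1.5)
  out <- murray_split(tr, 90)
  expect_equal(out$q, c(45, 45))
  # zero total
  expect_equal(murray_split(tr, 0)$q, c(0, 0))
})

test_that("Murray split is invariant under radius rescaling", {
  tr <- arch_branch_tree()
  a <- murray_split(tr, 181.5)
  b <- murray_split(arch_branch_tree(scale = 3.7), 181.5)
  expect_equal(a$q, b$q)
  expect_equal(sum(a$q), 181.5)
})

test_that("the arch level splits brachiocephalic-half by default", {
  tr <- arch_branch_tree()
  out <- murray_split(tr, 100)
  q <- setNames(out$q, out$name)
  expect_equal(as.numeric(q["left_common_carotid"]), 25)
  expect_equal(as.numeric(q["left_subclavian"]), 25)
  expect_equal(as.numeric(q["right_subclavian"] + q["right_common_carotid"]),
               50)
  out2 <- murray_split(tr, 99, arch_rule = "equal")
  q2 <- setNames(out2$q, out2$name)
  expect_equal(as.numeric(q2["left_common_carotid"]), 33)
  expect_equal(sum(out2$q), 99)
})

test_that("malformed branch trees are rejected", {
  bad <- data.frame(id = 1:2, parent = c(NA, 1), radius = c(1, 0))
  expect_error(murray_split(bad, 10), "> 0")
  cyc <- data.frame(id = 1:3, parent = c(NA, 3, 2), radius = c(1, 1, 1))
  expect_error(murray_split(cyc, 10), "cycle")
})

test_that("the sink band extracts exactly the asc-desc flow difference", {
  v <- build_vessel(r_ref = 0.012, d = 0.351)
  snk <- build_sink_band(v, 407, 225.5)
  expect_equal(snk$q_mls, 181.5)
  expect_equal(snk$v_n * snk$area / 1e-6, 181.5, tolerance = 1e-10)
  expect_equal(build_sink_band(v, 300, 300)$v_n, 0)
  # doubling the band length halves the velocity at identical flux
  v2 <- build_vessel(r_ref = 0.012, d = 0.351, branch_band = c(0.02, 0.08))
  snk2 <- build_sink_band(v2, 407, 225.5)
  expect_equal(snk2$v_n / snk$v_n, 0.5, tolerance = 1e-9)
  expect_equal(snk2$v_n * snk2$area, snk$v_n * snk$area)
  expect_error(build_sink_band(v, 200, 300), "collateral")
})

test_that("constructed boundary conditions close the global mass budget", {
  v <- build_vessel(r_ref = 0.01, d = 0.3, length = 0.06, l_s = 0.012,
                    z_s = 0.04, branch_band = c(0.015, 0.025))
  m <- generate_mesh(v, mesh_spec(delta = 1e-3))
  f <- solve_steady_flow(m, list(inlet = analytic_inlet(m, 40),
                                 sink = build_sink_band(v, 40, 22.2)),
                         rheology = newtonian(3.5e-3))
  expect_true(f$converged)
  fp <- flux_profile(f)
  # plane-by-plane: inlet flux minus upstream extraction, within 0.1 %
  expect_lt(max(abs(fp$q - fp$q_expected)) / 40, 1e-3)
  # inlet = sink + outlet
  expect_equal(fp$q[1], 40, tolerance = 1e-9)
  expect_equal(fp$q[length(fp$q)], 40 - 17.8, tolerance = 0.04)
})

test_that("boundary-condition sets serialize to JSON", {
  v <- build_vessel(r_ref = 0.012, d = 0.3)
  m <- generate_mesh(v, mesh_spec(delta = 1e-3))
  bcs <- list(inlet = analytic_inlet(m, 407),
              sink = build_sink_band(v, 407, 225.5))
  path <- withr::local_tempfile(fileext = ".json")
  write_bcs_json(m, bcs, path)
  js <- jsonlite::read_json(path)
  expect_equal(js$inlet$q_mls, 407)
  expect_equal(js$sink$q_mls, 181.5)
  expect_equal(js$outlet$q_mls, 225.5)
  expect_length(js$inlet$u_m_s, m$nr)
})
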