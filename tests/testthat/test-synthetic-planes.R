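test_that("synthetic planes integrate to the requested flow", {
  for (prof in list(list(k = 2, d = 0, s = 0),
                    list(k = 6, d = 0.3, s = 0.1),
                    list(k = 3.5, d = 0.55, sfd = 0.8))) {
    pl <- synthesize_plane(0.012, 407, profile = prof)
    expect_equal(plane_flow(pl), 407, tolerance = 0.005)
  }
  expect_error(synthesize_plane(0.012, 0), "> 0")
  expect_error(synthesize_plane(0.012, 400, profile = list(k = 2, d = 1.1)),
               "\\[0, 1\\)")
  expect_error(synthesize_plane(0.012, 400, profile = list(k = 1.2, d = 0)),
               ">= 2")
})

test_that("a centred symmetric plane has zero SFD and centred NFD", {
  pl <- synthesize_plane(0.012, 400, profile = list(k = 2, d = 0, s = 0))
  expect_equal(secondary_flow_degree(pl), 0)
  spacing <- diff(pl$x)[1] / pl$radius
  expect_lt(normalized_flow_displacement(pl), spacing)
  expect_lt(normalized_flow_displacement(pl, "flow_centroid"), 1e-10)
})

test_that("constructed SFD targets are met exactly and scale linearly", {
  pl <- synthesize_plane(0.012, 400, profile = list(k = 2, d = 0, sfd = 0.2))
  expect_equal(secondary_flow_degree(pl), 0.2)
  s <- attr(pl, "ground_truth")$s
  pl2 <- synthesize_plane(0.012, 400, profile = list(k = 2, d = 0, s = 2 * s))
  expect_equal(secondary_flow_degree(pl2), 0.4)
})

test_that("velocity-encoding aliasing wraps into (-venc, venc]", {
  # peak velocity ~4.4 m/s without aliasing
  fast <- synthesize_plane(0.012, 1600, profile = list(k = 8, d = 0))
  expect_gt(max(fast$vz), 4)
  wrapped <- synthesize_plane(0.012, 1600, profile = list(k = 8, d = 0),
                              venc = 4)
  expect_true(all(wrapped$vz[wrapped$mask] > -4))
  expect_true(all(wrapped$vz[wrapped$mask] <= 4))
  expect_true(any(wrapped$vz[wrapped$mask] < 0))  # genuine wrap-around
})

test_that("plane synthesis is deterministic in the seed", {
  a <- synthesize_plane(0.012, 400, noise_sd = 0.05, seed = 11)
  b <- synthesize_plane(0.012, 400, noise_sd = 0.05, seed = 11)
  c <- synthesize_plane(0.012, 400, noise_sd = 0.05, seed = 12)
  expect_identical(a$vz, b$vz)
  expect_false(identical(a$vz, c$vz))
})

test_that("plane CSV round trip preserves the field", {
  pl <- synthesize_plane(0.01, 300, profile = list(k = 4, d = 0.2, sfd = 0.5),
                         noise_sd = 0.03, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_velocity_plane(pl, path)
  back <- read_velocity_plane(path)
  expect_identical(back$vz, pl$vz)
  expect_identical(back$mask, pl$mask)
  expect_equal(back$radius, pl$radius)
})

test_that("a zero-variance spec reproduces the population means exactly", {
  spec <- cohort_distribution_spec(
    stenosis_sd = 0, bsa_sd = 0, age_sd = 0, hr_rest_sd = 0, hr_frac_sd = 0,
    svi_sd = 0, sbp_rest_sd = 0, sbp_inc_sd = 0, dbp_rest_sd = 0,
    dbp_inc_sd = 0, q_asc_sd = 0, ex_scale_sdlog = 0, desc_frac_sd = 0,
    desc_ex_scale_sdlog = 0, jet_d_sd = 0, sfd_sd = 0, p_male = 1)
  p <- sample_patient(spec, seed = 1, planes = FALSE)
  expect_equal(p$record$hr_rest, 72.9)
  expect_equal(p$record$hr_ex, 72.9 + 50 * 0.8579)
  expect_equal(degree_of_stenosis(p$geometry), 0.351, tolerance = 1e-6)
  expect_equal(p$record$q_asc_rest, 407)
  expect_equal(p$record$sv_rest, 50.6 * 1.6)
})

test_that("patient sampling is deterministic and respects invariants", {
  a <- sample_patient(seed = 5, id = 3, planes = TRUE)
  b <- sample_patient(seed = 5, id = 3, planes = TRUE)
  expect_identical(a$record, b$record)
  expect_identical(a$planes$rest$sinotubular$vz, b$planes$rest$sinotubular$vz)
  co <- sample_cohort(25, seed = 9)
  tab <- co$table$patients
  expect_true(all(tab$q_asc_ex >= 0))
  expect_true(all(tab$q_desc_rest <= tab$q_asc_rest))
  expect_true(all(tab$hr_ex > tab$hr_rest))
  expect_true(all(tab$bsa > 0))
})

test_that("cohort moments match the sampling distribution (Monte Carlo)", {
  spec <- cohort_distribution_spec()
  co <- sample_cohort(500, spec, seed = 123)
  sten <- sapply(co$patients, function(p) p$geometry$d)
  target <- truncnorm_mean(spec$stenosis_mean, spec$stenosis_sd,
                           spec$stenosis_bounds[1], spec$stenosis_bounds[2])
  se <- spec$stenosis_sd / sqrt(500)
  expect_lt(abs(mean(sten) - target), 3 * se)
  expect_lt(abs(mean(sten) - spec$stenosis_mean), 3 * se + 0.0115)
  q <- co$table$patients$q_asc_rest
  expect_lt(abs(mean(q) - spec$q_asc_mean), 3 * spec$q_asc_sd / sqrt(500) + 1)
})

test_that("invalid distribution specs are rejected before sampling", {
  expect_error(cohort_distribution_spec(noise_sd_ex = 0.01), "noise")
  expect_error(cohort_distribution_spec(hr_rest_sd = -1), "sds")
  expect_error(cohort_distribution_spec(stenosis_bounds = c(0, 0.99)),
               "0.95")
  expect_error(cohort_distribution_spec(nonsense = 1), "unknown")
})

test_that("noise-free metrics recover the generating parameters", {
  set.seed(77)
  spacing <- NULL
  for (rep in 1:25) {
    d <- runif(1, 0, 0.5)
    k <- runif(1, 2, 8)
    sfd <- runif(1, 0.05, 1)
    pl <- synthesize_plane(0.012, 350,
                           profile = list(k = k, d = d, sfd = sfd))
    spacing <- diff(pl$x)[1] / pl$radius
    expect_lt(abs(normalized_flow_displacement(pl) - d), spacing)
    expect_lt(abs(secondary_flow_degree(pl) - sfd) / sfd, 0.01)
  }
})

test_that("noisy-plane metric estimates are unbiased within MC error", {
  # flow-centroid NFD is linear in the noise, hence exactly unbiased;
  # verify by Monte Carlo and check the SFD bias stays below MC resolution
  d_true <- 0.25
  sfd_true <- 0.5
  nfd <- sfd <- numeric(200)
  for (s in 1:200) {
    pl <- synthesize_plane(0.012, 400,
                           profile = list(k = 4, d = d_true, sfd = sfd_true),
                           noise_sd = 0.02, seed = 1000 + s)
    nfd[s] <- normalized_flow_displacement(pl, "flow_centroid")
    sfd[s] <- secondary_flow_degree(pl)
  }
  ref <- synthesize_plane(0.012, 400,
                          profile = list(k = 4, d = d_true, sfd = sfd_true))
  nfd_ref <- normalized_flow_displacement(ref, "flow_centroid")
  expect_lt(abs(mean(nfd) - nfd_ref), 3 * sd(nfd) / sqrt(200) + 1e-4)
  expect_lt(abs(mean(sfd) - sfd_true), 3 * sd(sfd) / sqrt(200) + 0.005)
})

test_that("patient planes serialize with a manifest", {
  p <- sample_patient(seed = 3, id = 2, planes = TRUE)
  dir <- withr::local_tempdir()
  write_patient_planes(p, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$id, 2)
  expect_length(man$planes, 6)   # 3 stations x rest/exercise
  back <- read_velocity_plane(file.path(dir, man$planes$rest_descending$file))
  expect_identical(back$vz, p$planes$rest$descending$vz)
  expect_error(write_patient_planes(sample_patient(seed = 3, id = 2,
                                                   planes = FALSE), dir),
               "without")
})
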