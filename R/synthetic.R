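# truncated-normal draw by rejection; degenerates to the mean when sd = 0
rtruncnorm1 <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * (n - length(out)) + 8, mean, sd)
    out <- c(out, x[x > lo & x < hi])
  }
  out[seq_len(n)]
}

#' Cohort sampling distributions
#'
#' Population-level distributions used by the synthetic-patient generator.
#' The defaults emulate an adolescent/young-adult aortic-coarctation cohort
#' under MRI-ergometry: stenosis degree 35.1 +/- 18.1 % (truncated to keep
#' the throat open), body surface area 1.6 +/- 0.4 m^2, resting heart rate
#' 72.9 +/- 14.2 bpm, an exercise target of +50 bpm of which a fraction
#' 85.79 +/- 10.28 % is achieved, stroke volume index 50.6 +/- 6 ml/m^2,
#' resting peak-systolic ascending flow 407.0 +/- 87.3 ml/s with a lognormal
#' exercise-to-rest flow scale centred at the cohort ratio, a
#' descending-to-ascending flow fraction centred at 0.554, cuff pressures
#' matching the cohort means, velocity-plane profile parameters (jet
#' displacement, bluntness, swirl) spanning the observed NFD/SFD ranges,
#' per-component velocity noise that is larger during exercise (images
#' acquired under exercise are noisier), and a velocity-encoding limit of
#' 3 m/s raised to 4 m/s for severe stenoses.
#'
#' @param ... named overrides of any default listed above (see the source
#'   for the complete field list).
#' @return An object of class `cohort_distribution_spec`.
#' @export
cohort_distribution_spec <- function(...) {
  spec <- list(
    stenosis_mean = 0.351, stenosis_sd = 0.181,
    stenosis_bounds = c(0.001, 0.95),
    bsa_mean = 1.6, bsa_sd = 0.4, bsa_bounds = c(0.5, 3),
    age_mean = 21.5, age_sd = 13.7, age_bounds = c(8, 70),
    p_male = 0.65,
    hr_rest_mean = 72.9, hr_rest_sd = 14.2, hr_rest_bounds = c(35, 150),
    hr_increase = 50, hr_frac_mean = 0.8579, hr_frac_sd = 0.1028,
    hr_frac_bounds = c(0.02, 1.5),
    svi_mean = 50.6, svi_sd = 6, svi_bounds = c(20, 90),
    sbp_rest_mean = 128.5, sbp_rest_sd = 21.5,
    sbp_inc_mean = 30.2, sbp_inc_sd = 25,
    dbp_rest_mean = 64.8, dbp_rest_sd = 9.1,
    dbp_inc_mean = 14, dbp_inc_sd = 12,
    q_asc_mean = 407.0, q_asc_sd = 87.3, q_asc_bounds = c(100, 900),
    ex_scale_meanlog = log(494.4 / 407.0), ex_scale_sdlog = 0.13,
    desc_frac_mean = 0.554, desc_frac_sd = 0.12,
    desc_frac_bounds = c(0.15, 0.95),
    desc_ex_scale_meanlog = log(274.8 / 225.5), desc_ex_scale_sdlog = 0.13,
    jet_d_mean = 0.08, jet_d_sd = 0.06, jet_d_bounds = c(0, 0.6),
    jet_k_range = c(2, 8),
    sfd_mean = 0.46, sfd_sd = 0.39, sfd_bounds = c(0.02, 2),
    noise_sd_rest = 0.05, noise_sd_ex = 0.10,
    venc_low = 3, venc_high = 4, venc_switch = 0.4,
    plane_n = 64L
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(spec))
  if (length(unknown)) {
    stop("unknown spec fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  spec[names(override)] <- override
  sds <- spec[grepl("_sd$", names(spec))]
  if (any(unlist(sds) < 0)) stop("all sds must be >= 0", call. = FALSE)
  if (spec$noise_sd_ex < spec$noise_sd_rest) {
    stop("exercise noise must be >= rest noise", call. = FALSE)
  }
  if (spec$stenosis_bounds[1] <= 0 || spec$stenosis_bounds[2] >= 0.95 + 1e-9) {
    stop("stenosis truncation must keep the degree inside (0, 0.95)",
         call. = FALSE)
  }
  structure(spec, class = "cohort_distribution_spec")
}

#' Sample one synthetic patient
#'
#' Draws a full synthetic participant from a [cohort_distribution_spec()]:
#' a clinical record (rest/exercise heart rate, stroke volume, cuff
#' pressures, ascending/descending peak-systolic flows), a parametric
#' stenotic vessel geometry whose degree of stenosis comes from the cohort
#' distribution, and velocity-encoded measurement planes at the
#' sinotubular junction, mid-ascending and descending stations for both
#' conditions. Exercise planes reuse the rest profile shape with rescaled
#' velocity and larger noise. The noise-free ground truth (jet
#' displacement, swirl, target SFD) of every plane is retained for
#' parameter-recovery studies. All draws pass through a single RNG seeded
#' with `seed + id`, so cohorts are reproducible patient by patient.
#'
#' @param spec a [cohort_distribution_spec()].
#' @param seed integer base seed.
#' @param id patient id (also the seed offset).
#' @param planes generate measurement planes (set `FALSE` to sample the
#'   clinical record only, which is much faster for large cohorts).
#' @return An object of class `synthetic_patient` with elements `record`
#'   (one-row data.frame in the cohort-table schema), `geometry`, `planes`
#'   (nested list `rest`/`exercise` by station) and `ground_truth`.
#' @export
sample_patient <- function(spec = cohort_distribution_spec(), seed = 1L,
                           id = 1L, planes = TRUE) {
  stopifnot(inherits(spec, "cohort_distribution_spec"))
  if (missing(seed) && missing(id)) stop("a seed is required", call. = FALSE)
  with_seed(seed + id, {
    sten <- rtruncnorm1(1, spec$stenosis_mean, spec$stenosis_sd,
                        spec$stenosis_bounds[1], spec$stenosis_bounds[2])
    bsa <- rtruncnorm1(1, spec$bsa_mean, spec$bsa_sd,
                       spec$bsa_bounds[1], spec$bsa_bounds[2])
    age <- rtruncnorm1(1, spec$age_mean, spec$age_sd,
                       spec$age_bounds[1], spec$age_bounds[2])
    sex <- if (runif(1) < spec$p_male) "M" else "F"
    hr_rest <- rtruncnorm1(1, spec$hr_rest_mean, spec$hr_rest_sd,
                           spec$hr_rest_bounds[1], spec$hr_rest_bounds[2])
    frac <- rtruncnorm1(1, spec$hr_frac_mean, spec$hr_frac_sd,
                        spec$hr_frac_bounds[1], spec$hr_frac_bounds[2])
    hr_ex <- hr_rest + spec$hr_increase * frac
    svi <- rtruncnorm1(1, spec$svi_mean, spec$svi_sd,
                       spec$svi_bounds[1], spec$svi_bounds[2])
    sv_rest <- svi * bsa
    sv_ex <- sv_rest * if (spec$svi_sd == 0) 1 else
      exp(rnorm(1, log(52.2 / 50.6), 0.08))
    sbp_rest <- rtruncnorm1(1, spec$sbp_rest_mean, spec$sbp_rest_sd, 60, 260)
    sbp_ex <- sbp_rest + rtruncnorm1(1, spec$sbp_inc_mean, spec$sbp_inc_sd,
                                     -30, 140)
    dbp_rest <- rtruncnorm1(1, spec$dbp_rest_mean, spec$dbp_rest_sd, 30, 140)
    dbp_ex <- dbp_rest + rtruncnorm1(1, spec$dbp_inc_mean, spec$dbp_inc_sd,
                                     -30, 80)
    q_asc_rest <- rtruncnorm1(1, spec$q_asc_mean, spec$q_asc_sd,
                              spec$q_asc_bounds[1], spec$q_asc_bounds[2])
    ex_scale <- if (spec$ex_scale_sdlog == 0) exp(spec$ex_scale_meanlog) else
      rlnorm(1, spec$ex_scale_meanlog, spec$ex_scale_sdlog)
    q_asc_ex <- q_asc_rest * ex_scale
    desc_frac <- rtruncnorm1(1, spec$desc_frac_mean, spec$desc_frac_sd,
                             spec$desc_frac_bounds[1],
                             spec$desc_frac_bounds[2])
    q_desc_rest <- q_asc_rest * desc_frac
    desc_scale <- if (spec$desc_ex_scale_sdlog == 0)
      exp(spec$desc_ex_scale_meanlog) else
      rlnorm(1, spec$desc_ex_scale_meanlog, spec$desc_ex_scale_sdlog)
    q_desc_ex <- min(q_desc_rest * desc_scale, 0.98 * q_asc_ex)

    r_ref <- 0.012 * sqrt(bsa / 1.6)    # aortic root scales with body size
    geometry <- build_vessel(r_ref = r_ref, d = sten)
    venc <- if (sten >= spec$venc_switch) spec$venc_high else spec$venc_low

    stations <- c("sinotubular", "mid_ascending", "descending")
    gt <- list()
    plane_list <- NULL
    if (planes) {
      prof <- lapply(stations, function(st) {
        list(d = rtruncnorm1(1, spec$jet_d_mean, spec$jet_d_sd,
                             spec$jet_d_bounds[1], spec$jet_d_bounds[2]),
             k = runif(1, spec$jet_k_range[1], spec$jet_k_range[2]),
             sfd = rtruncnorm1(1, spec$sfd_mean, spec$sfd_sd,
                               spec$sfd_bounds[1], spec$sfd_bounds[2]))
      })
      names(prof) <- stations
      seeds <- matrix(sample.int(.Machine$integer.max - 1L, 6), 2, 3)
      radii <- c(sinotubular = r_ref, mid_ascending = r_ref,
                 descending = 0.8 * r_ref)
      q_rest <- c(q_asc_rest, q_asc_rest, q_desc_rest)
      q_ex <- c(q_asc_ex, q_asc_ex, q_desc_ex)
      make <- function(cond) {
        out <- lapply(seq_along(stations), function(s) {
          synthesize_plane(
            radius = radii[s],
            q_mls = if (cond == "rest") q_rest[s] else q_ex[s],
            profile = prof[[stations[s]]],
            noise_sd = if (cond == "rest") spec$noise_sd_rest else
              spec$noise_sd_ex,
            venc = venc,
            seed = seeds[if (cond == "rest") 1 else 2, s],
            n = spec$plane_n)
        })
        names(out) <- stations
        out
      }
      plane_list <- list(rest = make("rest"), exercise = make("exercise"))
      gt <- prof
    }

    record <- data.frame(
      id = id, bsa = bsa, sex = sex, age = age,
      sbp_rest = sbp_rest, sbp_ex = sbp_ex,
      dbp_rest = dbp_rest, dbp_ex = dbp_ex,
      hr_rest = hr_rest, hr_ex = hr_ex,
      sv_rest = sv_rest, sv_ex = sv_ex,
      q_asc_rest = q_asc_rest, q_asc_ex = q_asc_ex,
      q_desc_rest = q_desc_rest, q_desc_ex = q_desc_ex,
      stringsAsFactors = FALSE)
    structure(list(record = record, geometry = geometry, planes = plane_list,
                   ground_truth = gt, venc = venc, seed = seed, id = id),
              class = "synthetic_patient")
  })
}

#' Sample a synthetic cohort
#'
#' Draws `n` patients via [sample_patient()] (seeds `seed + 1 .. seed + n`)
#' and assembles their clinical records into a [cohort_table()].
#'
#' @param n number of patients.
#' @param spec a [cohort_distribution_spec()].
#' @param seed integer base seed.
#' @param planes whether to generate measurement planes per patient.
#' @return A list with `patients` (list of `synthetic_patient`) and `table`
#'   (a [cohort_table()]).
#' @export
sample_cohort <- function(n, spec = cohort_distribution_spec(), seed = 1L,
                          planes = FALSE) {
  pts <- lapply(seq_len(n), function(i) {
    sample_patient(spec, seed = seed, id = i, planes = planes)
  })
  tab <- cohort_table(do.call(rbind, lapply(pts, `[[`, "record")))
  list(patients = pts, table = tab)
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat(sprintf(
    "<synthetic_patient> id %d: stenosis %.1f%%, HR %.0f -> %.0f bpm, Q_asc %.0f -> %.0f ml/s\n",
    x$id, 100 * x$geometry$d, x$record$hr_rest, x$record$hr_ex,
    x$record$q_asc_rest, x$record$q_asc_ex))
  invisible(x)
}
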