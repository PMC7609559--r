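#' @importFrom stats approx sd setNames rnorm runif rlnorm shapiro.test t.test
#'   wilcox.test quantile
#' @importFrom utils read.csv write.csv
NULL

# Documented CSV schema (one header row, comma separated, dot decimal).
# Patient columns are required; hemodynamic-metric columns are optional and
# may be empty on a per-row basis (missing value, never zero).
patient_cols <- c(
  "id", "bsa", "sex", "age",
  "sbp_rest", "sbp_ex", "dbp_rest", "dbp_ex",
  "hr_rest", "hr_ex", "sv_rest", "sv_ex",
  "q_asc_rest", "q_asc_ex", "q_desc_rest", "q_desc_ex"
)
metric_cols <- c(
  "pg_rest", "pg_ex", "wss_rest", "wss_ex",
  "sfd_asc_rest", "sfd_asc_ex", "sfd_desc_rest", "sfd_desc_ex",
  "nfd_asc_rest", "nfd_asc_ex", "nfd_desc_rest", "nfd_desc_ex"
)

#' Assemble a patient cohort table
#'
#' Bundles per-patient clinical measurements and (optionally) CFD-derived
#' hemodynamic metrics into a validated `cohort_table` object. All values are
#' kept in clinical units: pressures in mmHg, heart rate in 1/min, stroke
#' volume in ml, peak-systolic flows in ml/s, wall shear stress in Pa,
#' secondary flow degree and normalized flow displacement dimensionless.
#'
#' Validation enforces: unique ids; `bsa`, heart rates and stroke volumes
#' strictly positive; wall shear stress, SFD and NFD non-negative; metric ids
#' a subset of patient ids. A descending flow exceeding the ascending flow is
#' physiologically possible with collateral circulation and is therefore
#' flagged with a warning rather than rejected.
#'
#' @param patients data.frame with columns `id, bsa, sex, age, sbp_rest,
#'   sbp_ex, dbp_rest, dbp_ex, hr_rest, hr_ex, sv_rest, sv_ex, q_asc_rest,
#'   q_asc_ex, q_desc_rest, q_desc_ex`.
#' @param metrics optional data.frame with columns `id, pg_rest, pg_ex,
#'   wss_rest, wss_ex, sfd_asc_rest, sfd_asc_ex, sfd_desc_rest, sfd_desc_ex,
#'   nfd_asc_rest, nfd_asc_ex, nfd_desc_rest, nfd_desc_ex`.
#' @return An object of class `cohort_table` with elements `patients` and
#'   `metrics`.
#' @export
cohort_table <- function(patients, metrics = NULL) {
  missing_cols <- setdiff(patient_cols, names(patients))
  if (length(missing_cols)) {
    stop("patient table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(patients$id)) {
    stop("duplicate patient id: ",
         paste(unique(patients$id[duplicated(patients$id)]), collapse = ", "),
         call. = FALSE)
  }
  check_pos <- function(col) {
    x <- patients[[col]]
    bad <- which(!is.na(x) & x <= 0)
    if (length(bad)) {
      stop(sprintf("row %d, column '%s': value must be > 0", bad[1], col),
           call. = FALSE)
    }
  }
  for (col in c("bsa", "hr_rest", "hr_ex", "sv_rest", "sv_ex")) check_pos(col)
  for (cond in c("rest", "ex")) {
    qa <- patients[[paste0("q_asc_", cond)]]
    qd <- patients[[paste0("q_desc_", cond)]]
    coll <- which(!is.na(qa) & !is.na(qd) & qd > qa)
    if (length(coll)) {
      warning("descending flow exceeds ascending flow (possible collateral ",
              "flow) at ", cond, " for patient id(s): ",
              paste(patients$id[coll], collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(metrics)) {
    metrics <- patients[0, "id", drop = FALSE]
    for (col in metric_cols) metrics[[col]] <- numeric(0)
  } else {
    missing_cols <- setdiff(c("id", metric_cols), names(metrics))
    if (length(missing_cols)) {
      stop("metrics table lacks columns: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    if (anyDuplicated(metrics$id)) {
      stop("duplicate metrics id", call. = FALSE)
    }
    if (!all(metrics$id %in% patients$id)) {
      stop("metrics contain ids absent from the patient table", call. = FALSE)
    }
    for (col in metric_cols) {
      x <- metrics[[col]]
      bad <- which(!is.na(x) & x < 0)
      if (length(bad)) {
        stop(sprintf("metrics row %d, column '%s': value must be >= 0",
                     bad[1], col), call. = FALSE)
      }
    }
    metrics <- metrics[, c("id", metric_cols)]
  }
  structure(
    list(patients = patients[, patient_cols], metrics = metrics),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> ", nrow(x$patients), " patients, ",
      nrow(x$metrics), " with hemodynamic metrics\n", sep = "")
  invisible(x)
}

#' Number of patients in a cohort table
#' @param x a `cohort_table`.
#' @export
n_patients <- function(x) nrow(x$patients)

#' Read a cohort table from CSV
#'
#' Reads the documented comma-separated schema (one header row, dot decimal,
#' UTF-8; column names as in [cohort_table()]). Metric columns may be absent
#' entirely, or empty per cell; empty cells become `NA`, never zero. Rows in
#' which every metric cell is empty contribute a patient but no metrics row.
#'
#' @param path path to a CSV file.
#' @return A [cohort_table()].
#' @export
load_cohort_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  check.names = TRUE)
  missing_cols <- setdiff(patient_cols, names(raw))
  if (length(missing_cols)) {
    stop("header lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num_cols <- c(setdiff(patient_cols, c("id", "sex")),
                intersect(metric_cols, names(raw)))
  for (col in num_cols) {
    txt <- trimws(raw[[col]])
    val <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.na(txt) & txt != "" & is.na(val))
    if (length(bad)) {
      stop(sprintf("row %d, column '%s': cannot parse '%s' as a number",
                   bad[1], col, txt[bad[1]]), call. = FALSE)
    }
    raw[[col]] <- val
  }
  patients <- raw[, patient_cols]
  present <- intersect(metric_cols, names(raw))
  metrics <- NULL
  if (length(present) && nrow(raw)) {
    full <- raw[, c("id", present)]
    for (col in setdiff(metric_cols, present)) full[[col]] <- NA_real_
    keep <- rowSums(!is.na(full[, metric_cols, drop = FALSE])) > 0
    if (any(keep)) metrics <- full[keep, c("id", metric_cols)]
  }
  cohort_table(patients, metrics)
}

#' Write a cohort table to CSV
#'
#' Inverse of [load_cohort_table()]: one row per patient, metric cells joined
#' by id, missing values written as empty cells. Numeric values are written
#' with 17 significant digits so that a write-then-read round trip is
#' lossless.
#'
#' @param cohort a [cohort_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  out <- merge(cohort$patients, cohort$metrics, by = "id", all.x = TRUE,
               sort = FALSE)
  out <- out[match(cohort$patients$id, out$id), ]
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), "",
                           sprintf("%.17g", out[[col]]))
    }
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Load the packaged reference cohort
#'
#' A transcribed 20-patient aortic-coarctation MRI-ergometry cohort: body
#' surface area, sex, age, right-arm cuff pressures, heart rate, stroke
#' volume and peak-systolic ascending/descending aortic flow at rest and
#' during exercise, together with CFD-derived transstenotic pressure
#' gradient, surface-averaged ascending-aorta wall shear stress, secondary
#' flow degree and normalized flow displacement (ascending and descending
#' stations) for both conditions.
#'
#' @return A [cohort_table()] with 20 patients, all with metrics.
#' @export
load_reference_cohort <- function() {
  path <- system.file("extdata", "coarctation_cohort.csv",
                      package = "coarctflow", mustWork = TRUE)
  load_cohort_table(path)
}
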