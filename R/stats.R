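#' Normality-routed paired comparison
#'
#' Compares a variable between rest and exercise across paired patients.
#' Normality of the paired differences is examined with the Shapiro-Wilk
#' test; normally distributed differences (p >= `alpha`) are tested with a
#' paired t-test, non-normal ones with the Wilcoxon signed-rank test
#' (zero differences dropped; exact distribution for 25 or fewer non-zero
#' untied differences, otherwise the normal approximation with continuity
#' correction). Identical rest and exercise vectors yield a degenerate
#' comparison with p = 1.
#'
#' @param rest,exercise paired measurement vectors (same patient order).
#' @param alpha significance level for the normality routing (default 0.05).
#' @param variable optional variable name carried into the result.
#' @return An object of class `paired_comparison`: sample size, rest and
#'   exercise mean +/- SD, Shapiro-Wilk p, the test used, its p-value, the
#'   percent change (mean of per-patient relative changes), and the percent
#'   change of the means.
#' @export
paired_compare <- function(rest, exercise, alpha = 0.05,
                           variable = NA_character_) {
  if (length(rest) != length(exercise)) {
    stop("rest and exercise must have equal length", call. = FALSE)
  }
  keep <- !is.na(rest) & !is.na(exercise)
  rest <- rest[keep]; exercise <- exercise[keep]
  n <- length(rest)
  if (n < 2) stop("need at least 2 complete pairs", call. = FALSE)
  d <- exercise - rest
  out <- list(variable = variable, n = n,
              mean_rest = mean(rest), sd_rest = sd(rest),
              mean_ex = mean(exercise), sd_ex = sd(exercise),
              normality_p = NA_real_, test = NA_character_,
              p_value = NA_real_, degenerate = FALSE,
              pct_change = if (all(rest != 0)) {
                mean(100 * (exercise - rest) / rest)
              } else NA_real_,
              pct_change_of_means = if (mean(rest) != 0) {
                100 * (mean(exercise) - mean(rest)) / mean(rest)
              } else NA_real_)
  if (all(d == 0)) {
    out$test <- "degenerate"
    out$p_value <- 1
    out$degenerate <- TRUE
    return(structure(out, class = "paired_comparison"))
  }
  sw <- if (n >= 3 && sd(d) > 0) {
    tryCatch(shapiro.test(d)$p.value, error = function(e) NA_real_)
  } else NA_real_
  out$normality_p <- sw
  if (!is.na(sw) && sw >= alpha) {
    out$test <- "paired t"
    out$p_value <- t.test(exercise, rest, paired = TRUE)$p.value
  } else {
    out$test <- "Wilcoxon signed-rank"
    out$p_value <- signed_rank_p(d)
  }
  structure(out, class = "paired_comparison")
}

# two-sided Wilcoxon signed-rank p-value for a vector of paired differences:
# zero differences dropped, exact distribution for <= 25 non-zero untied
# differences, otherwise normal approximation with continuity correction
signed_rank_p <- function(d) {
  nz <- d[d != 0]
  if (!length(nz)) return(1)
  exact_ok <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  suppressWarnings(
    wilcox.test(nz, exact = exact_ok, correct = TRUE)$p.value)
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf(
    "%s: %.3g +/- %.3g -> %.3g +/- %.3g (%s, p = %.3g, change %+.1f%%)\n",
    if (is.na(x$variable)) "paired comparison" else x$variable,
    x$mean_rest, x$sd_rest, x$mean_ex, x$sd_ex, x$test, x$p_value,
    x$pct_change))
  invisible(x)
}

#' Mean per-patient percent change
#'
#' The cohort percent change reported here is the mean of the per-patient
#' relative changes, `mean(100 * (exercise - rest) / rest)` (not the
#' relative change of the cohort means, which [paired_compare()] also
#' reports).
#'
#' @param rest,exercise paired measurement vectors; every rest value must be
#'   non-zero.
#' @return percent change.
#' @export
percent_change <- function(rest, exercise) {
  if (length(rest) != length(exercise)) {
    stop("rest and exercise must have equal length", call. = FALSE)
  }
  bad <- which(rest == 0)
  if (length(bad)) {
    stop("rest value is zero for pair(s) ", paste(bad, collapse = ", "),
         ": relative change undefined", call. = FALSE)
  }
  mean(100 * (exercise - rest) / rest)
}

#' Classify gradients against the intervention threshold
#'
#' Counts patients whose transstenotic pressure gradient lies above the
#' intervention threshold (strictly greater than, default 20 mmHg) at both
#' rest and exercise, below at both, or crosses the threshold from rest to
#' exercise; reverse crossings (above at rest, at or below during exercise)
#' are counted separately. The four counts always sum to the number of
#' pairs.
#'
#' @param pg_rest,pg_ex paired pressure gradients, mmHg.
#' @param threshold intervention threshold, mmHg.
#' @return list with `both_above`, `both_below`, `crossed`,
#'   `reverse_crossed` and `n`.
#' @export
classify_threshold <- function(pg_rest, pg_ex, threshold = 20) {
  if (length(pg_rest) != length(pg_ex)) {
    stop("paired vectors required", call. = FALSE)
  }
  keep <- !is.na(pg_rest) & !is.na(pg_ex)
  pg_rest <- pg_rest[keep]; pg_ex <- pg_ex[keep]
  list(
    both_above = sum(pg_rest > threshold & pg_ex > threshold),
    both_below = sum(pg_rest <= threshold & pg_ex <= threshold),
    crossed = sum(pg_rest <= threshold & pg_ex > threshold),
    reverse_crossed = sum(pg_rest > threshold & pg_ex <= threshold),
    n = length(pg_rest)
  )
}

#' Rest-versus-exercise cohort summary
#'
#' Runs the full statistical stage on a cohort: per-variable rest/exercise
#' means +/- SD, normality-routed paired tests and percent changes for
#' heart rate, stroke volume index, cardiac index, cuff pressures,
#' ascending and descending peak-systolic flow, transstenotic pressure
#' gradient, surface-averaged wall shear stress, and secondary flow degree
#' and normalized flow displacement at the ascending and descending
#' stations, plus the 20 mmHg intervention-threshold classification of the
#' gradients.
#'
#' @param cohort a [cohort_table()] whose metrics table is populated.
#' @param alpha significance level.
#' @param threshold intervention threshold, mmHg.
#' @return An object of class `cohort_summary`: `comparisons` (named list
#'   of [paired_compare()] results), `threshold` (classification counts)
#'   and `n`.
#' @export
summarize_rest_exercise <- function(cohort, alpha = 0.05, threshold = 20) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!nrow(cohort$metrics)) {
    stop("cohort has no hemodynamic metrics", call. = FALSE)
  }
  d <- merge(cohort$patients, cohort$metrics, by = "id")
  d$svi_rest <- stroke_volume_index(d$sv_rest, d$bsa)
  d$svi_ex <- stroke_volume_index(d$sv_ex, d$bsa)
  d$ci_rest <- cardiac_index(d$hr_rest, d$sv_rest, d$bsa)
  d$ci_ex <- cardiac_index(d$hr_ex, d$sv_ex, d$bsa)
  vars <- c(hr = "hr", svi = "svi", ci = "ci", sbp = "sbp", dbp = "dbp",
            q_asc = "q_asc", q_desc = "q_desc", pg = "pg", wss = "wss",
            sfd_asc = "sfd_asc", sfd_desc = "sfd_desc",
            nfd_asc = "nfd_asc", nfd_desc = "nfd_desc")
  need <- c(paste0(vars, "_rest"), paste0(vars, "_ex"))
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop("cohort lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  comparisons <- lapply(names(vars), function(v) {
    paired_compare(d[[paste0(v, "_rest")]], d[[paste0(v, "_ex")]],
                   alpha = alpha, variable = v)
  })
  names(comparisons) <- names(vars)
  structure(
    list(comparisons = comparisons,
         threshold = classify_threshold(d$pg_rest, d$pg_ex, threshold),
         threshold_mmHg = threshold, n = nrow(d)),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> n =", x$n, "\n")
  for (cmp in x$comparisons) print(cmp)
  th <- x$threshold
  cat(sprintf(
    "gradient > %g mmHg: %d at both conditions, %d at neither, %d crossed during exercise (%d reverse)\n",
    x$threshold_mmHg, th$both_above, th$both_below, th$crossed,
    th$reverse_crossed))
  invisible(x)
}

#' Write a cohort summary to JSON
#'
#' Serializes a [summarize_rest_exercise()] result: one object per variable
#' with fields `mean_rest, sd_rest, mean_ex, sd_ex, test, p, pct_change,
#' pct_change_of_means`, plus the threshold classification.
#'
#' @param summary a `cohort_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  stopifnot(inherits(summary, "cohort_summary"))
  rows <- lapply(summary$comparisons, function(cmp) {
    list(mean_rest = cmp$mean_rest, sd_rest = cmp$sd_rest,
         mean_ex = cmp$mean_ex, sd_ex = cmp$sd_ex, test = cmp$test,
         p = cmp$p_value, pct_change = cmp$pct_change,
         pct_change_of_means = cmp$pct_change_of_means)
  })
  jsonlite::write_json(
    list(n = summary$n, variables = rows,
         threshold_mmHg = summary$threshold_mmHg,
         threshold = summary$threshold),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
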