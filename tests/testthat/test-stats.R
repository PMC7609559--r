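test_that("signed-rank p equals brute-force enumeration for n <= 8", {
  mags <- list(c(1.3, 2.1, 0.4, 3.3, 5.2, 0.9),
               c(0.2, 1.1, 2.7, 3.9, 4.4, 6.1, 7.3, 8.8))
  for (m in mags) {
    n <- length(m)
    for (pattern in 0:(2^n - 1)) {
      signs <- ifelse(bitwAnd(pattern, 2^(0:(n - 1))) > 0, 1, -1)
      d <- m * signs
      expect_equal(coarctflow:::signed_rank_p(d), signed_rank_enum_p(d),
                   tolerance = 1e-12,
                   label = paste("pattern", pattern, "n", n))
    }
  }
})

test_that("normality routing picks the expected test", {
  # normal differences -> paired t; the routing probability is exactly
  # P(Shapiro p >= 0.05) = 0.95, so allow binomial Monte-Carlo slack
  picks <- withr::with_seed(42, replicate(500, {
    d <- rnorm(20)
    paired_compare(rep(0, 20), d)$test
  }))
  expect_gte(mean(picks == "paired t"), 0.95 - 3 * sqrt(0.95 * 0.05 / 500))
  # heavy-tailed differences -> Wilcoxon in at least 95 %
  picks <- withr::with_seed(43, replicate(500, {
    d <- rcauchy(50)
    paired_compare(rep(0, 50), d)$test
  }))
  expect_gte(mean(picks == "Wilcoxon signed-rank"), 0.95)
})

test_that("degenerate and malformed comparisons are handled", {
  x <- c(3, 1, 4, 1, 5)
  cmp <- paired_compare(x, x)
  expect_true(cmp$degenerate)
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$pct_change, 0)
  expect_error(paired_compare(1:4, 1:5), "equal length")
  expect_error(paired_compare(1, 2), "at least 2")
})

test_that("percent change averages per-patient relative changes", {
  expect_equal(percent_change(c(10, 20), c(20, 20)), 50)
  expect_equal(percent_change(c(5, 9, 13), c(5, 9, 13)), 0)
  expect_error(percent_change(c(1, 0), c(2, 2)), "pair\\(s\\) 2")
  co <- load_reference_cohort()
  pc <- percent_change(co$metrics$pg_rest, co$metrics$pg_ex)
  expect_equal(pc, 75, tolerance = 0.02)   # integer-rounded inputs
})

test_that("threshold classification reproduces the cohort partition", {
  co <- load_reference_cohort()
  th <- classify_threshold(co$metrics$pg_rest, co$metrics$pg_ex, 20)
  expect_identical(th$both_above, 6L)
  expect_identical(th$both_below, 8L)
  expect_identical(th$crossed, 6L)
  expect_identical(th$reverse_crossed, 0L)
  expect_identical(th$both_above + th$both_below + th$crossed +
                     th$reverse_crossed, th$n)
  zero <- classify_threshold(rep(0, 7), rep(0, 7))
  expect_identical(zero$both_below, 7L)
  # counts always partition n, including reverse crossings
  rnd <- withr::with_seed(7, classify_threshold(runif(50, 0, 40),
                                                runif(50, 0, 40)))
  expect_identical(rnd$both_above + rnd$both_below + rnd$crossed +
                     rnd$reverse_crossed, 50L)
})

test_that("the cohort summary is permutation invariant and typed", {
  co <- load_reference_cohort()
  s <- summarize_rest_exercise(co)
  perm <- withr::with_seed(1, sample(20))
  co2 <- cohort_table(co$patients[perm, ], co$metrics[rev(perm), ])
  s2 <- summarize_rest_exercise(co2)
  for (v in names(s$comparisons)) {
    expect_equal(s2$comparisons[[v]]$mean_rest, s$comparisons[[v]]$mean_rest)
    expect_equal(s2$comparisons[[v]]$p_value, s$comparisons[[v]]$p_value)
  }
  expect_identical(s2$threshold, s$threshold)
  # degenerate synthetic cohort: zero variance -> zero SDs
  spec0 <- cohort_distribution_spec(
    stenosis_sd = 0, bsa_sd = 0, age_sd = 0, hr_rest_sd = 0, hr_frac_sd = 0,
    svi_sd = 0, sbp_rest_sd = 0, sbp_inc_sd = 0, dbp_rest_sd = 0,
    dbp_inc_sd = 0, q_asc_sd = 0, ex_scale_sdlog = 0, desc_frac_sd = 0,
    desc_ex_scale_sdlog = 0, jet_d_sd = 0, sfd_sd = 0, p_male = 1)
  tab <- sample_cohort(4, spec0, seed = 2)$table
  cmp <- paired_compare(tab$patients$hr_rest, tab$patients$hr_ex)
  expect_equal(cmp$sd_rest, 0)
  expect_equal(cmp$sd_ex, 0)
  # missing metrics are an error, not silence
  expect_error(summarize_rest_exercise(cohort_table(co$patients)),
               "no hemodynamic metrics")
})

test_that("cohort summaries serialize to JSON", {
  s <- summarize_rest_exercise(load_reference_cohort())
  path <- withr::local_tempfile(fileext = ".json")
  write_summary_json(s, path)
  js <- jsonlite::read_json(path)
  expect_equal(js$n, 20)
  expect_equal(js$variables$pg$mean_rest, 18, tolerance = 1e-9)
  expect_identical(js$threshold$both_above, 6L)
  expect_true(all(c("test", "p", "pct_change") %in%
                    names(js$variables$wss)))
})
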