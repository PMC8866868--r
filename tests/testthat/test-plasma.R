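panel <- load_panel()

make_trio <- function(n_informative, family_id = "F1") {
  purrr::map_dfr(seq_len(nrow(panel)), function(i) {
    row <- panel[i, ]
    a <- strsplit(row$snp1_alleles, "/", fixed = TRUE)[[1]]
    b <- strsplit(row$snp2_alleles, "/", fixed = TRUE)[[1]]
    hap_m <- paste0(a[1], b[1])
    hap_f <- paste0(a[2], b[2])
    if (i <= n_informative) {
      tibble::tibble(family_id = family_id, locus_id = row$locus_id,
                     mother = paste(hap_m, hap_m, sep = "-"),
                     father = paste(hap_f, hap_f, sep = "-"),
                     child = paste(sort(c(hap_m, hap_f)), collapse = "-"))
    } else {
      tibble::tibble(family_id = family_id, locus_id = row$locus_id,
                     mother = paste(hap_m, hap_m, sep = "-"),
                     father = paste(hap_m, hap_m, sep = "-"),
                     child = paste(hap_m, hap_m, sep = "-"))
    }
  })
}

plasma_row <- function(family_id = "F1", conc = 0.6, ff = 0.12) {
  tibble::tibble(family_id = family_id, cfdna_conc_ng_per_ul = conc,
                 fetal_fraction = ff, lognormal_median_bp = 143,
                 lognormal_sigma = 0.30)
}

test_that("an ample-template family detects all its informative markers", {
  trio <- make_trio(6)
  report <- run_family(trio, plasma_row(), panel, deterministic = TRUE)
  expect_equal(attr(report, "expected_count"), 6L)
  expect_equal(attr(report, "observed_count"), 6L)
  expect_true(all(report$detected))
  expect_true(all(report$observed_size_bp >= 26 &
                    report$observed_size_bp <= 77))
})

test_that("a family with no informative marker reports zero, not an error", {
  trio <- make_trio(0)
  report <- run_family(trio, plasma_row(), panel, deterministic = TRUE)
  expect_equal(attr(report, "expected_count"), 0L)
  expect_equal(attr(report, "observed_count"), 0L)
  expect_equal(nrow(report), 0)
})

test_that("very low template can drop a single marker", {
  trio <- make_trio(2)
  # below the quantitation floor, with a minimal fetal fraction
  starved <- plasma_row(conc = 0.02, ff = 0.05)
  report <- run_family(trio, starved, panel, deterministic = TRUE)
  expect_lt(attr(report, "observed_count"), attr(report, "expected_count"))
  expect_true(all(report$height_rfu > 0))
})

test_that("observed never exceeds expected and the run is seed-stable", {
  set.seed(101)
  freqs <- synth_frequencies(panel)
  cohort <- generate_cohort(freqs, 8)
  plasma <- generate_plasma(cohort)
  run <- run_cohort(cohort, plasma, panel)
  expect_true(all(run$families$observed_count <=
                    run$families$expected_count))
  expect_true(all(run$families$expected_count <= 15))

  set.seed(55); r1 <- run_cohort(cohort, plasma, panel)
  set.seed(55); r2 <- run_cohort(cohort, plasma, panel)
  expect_identical(r1$outcomes, r2$outcomes)
  expect_identical(glance(summarize_cohort(r1)),
                   glance(summarize_cohort(r2)))
})

test_that("the bundled accounting table reproduces the published totals", {
  counts <- load_family_counts()
  s <- summarize_cohort(counts)
  expect_equal(s$total_expected, 77L)
  expect_equal(s$total_observed, 76L)
  expect_equal(s$detection_rate_percent, 98.7)

  g <- glance(s)
  expect_equal(g$n_families, 26L)
  t <- tidy(s)
  expect_equal(nrow(t), 26)
  expect_equal(t$detected_fraction[t$family_id == "2"], 0.5)
  expect_true(is.na(t$detected_fraction[t$family_id == "24"]))
})

test_that("summaries reject impossible accounting and empty input", {
  bad <- tibble::tibble(family_id = "1", expected_count = 1,
                        observed_count = 2)
  expect_error(summarize_cohort(bad), class = "snpsnpmix_validation_error")
  expect_error(summarize_cohort(bad[0, ]),
               class = "snpsnpmix_validation_error")
  none <- tibble::tibble(family_id = "1", expected_count = 0,
                         observed_count = 0)
  expect_true(is.na(summarize_cohort(none)$detection_rate_percent))
})

test_that("per-primer tallies sum to the attempted reactions", {
  set.seed(202)
  cohort <- generate_cohort(synth_frequencies(panel), 10)
  plasma <- generate_plasma(cohort)
  run <- run_cohort(cohort, plasma, panel)
  tallies <- primer_detection_rates(run)
  expect_equal(sum(tallies$total), sum(run$families$expected_count))
  expect_equal(sum(tallies$successful), sum(run$families$observed_count))
  expect_true(all(tallies$rate >= 0 & tallies$rate <= 1))

  # the bundled usage report carries its own tallies
  fixture <- primer_detection_rates(load_primer_report())
  expect_equal(fixture$rate[fixture$primer_id == "MH3-F1"], 0.5)
  expect_equal(sum(fixture$total), 77L)
  expect_equal(sum(fixture$successful), 76L)
})

test_that("concentration-detection association is descriptive and sane", {
  counts <- load_family_counts()
  rep1 <- correlation_report(counts)
  expect_equal(rep1$n_families, 24L)  # 25 quantified minus family 24
  # the one missed marker belongs to the unquantified family, so every
  # remaining detected fraction is 1: flagged, not spuriously correlated
  expect_true(rep1$zero_variance)

  # full detection regardless of concentration: zero variance flagged
  flat <- tibble::tibble(family_id = as.character(1:5),
                         cfdna_conc_ng_per_ul = c(0.2, 0.4, 0.6, 0.8, 1),
                         expected_count = 3, observed_count = 3)
  expect_true(correlation_report(flat)$zero_variance)

  # concentration-driven dropout yields a positive coefficient
  set.seed(66)
  n <- 40
  conc <- runif(n, 0.1, 1.4)
  expected <- rep(5, n)
  observed <- vapply(conc, function(cc)
    rbinom(1, 5, prob = min(1, cc * 2)), integer(1))
  driven <- tibble::tibble(family_id = as.character(seq_len(n)),
                           cfdna_conc_ng_per_ul = conc,
                           expected_count = expected,
                           observed_count = observed)
  expect_gt(correlation_report(driven)$spearman_rho, 0.3)

  # independent dropout stays near zero
  indep <- tibble::tibble(family_id = as.character(seq_len(n)),
                          cfdna_conc_ng_per_ul = conc,
                          expected_count = expected,
                          observed_count = rbinom(n, 5, 0.8))
  expect_lt(abs(correlation_report(indep)$spearman_rho), 0.35)

  expect_error(correlation_report(flat[1:2, ]),
               class = "snpsnpmix_validation_error")
})
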