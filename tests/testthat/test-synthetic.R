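panel <- load_panel()

test_that("synthetic frequencies are valid and respect the MAF range", {
  set.seed(1)
  freqs <- synth_frequencies(panel)
  expect_silent(validate_frequencies(freqs))
  expect_equal(dplyr::n_distinct(freqs$locus_id), 15)
  marg <- snp1_marginals(freqs)
  expect_true(all(marg$freq > 0.25 & marg$freq < 0.75))
})

test_that("generated cohorts are Mendelian-consistent and reproducible", {
  set.seed(2)
  freqs <- synth_frequencies(panel)
  cohort <- generate_cohort(freqs, n_families = 26)
  expect_equal(dplyr::n_distinct(cohort$family_id), 26)
  expect_equal(nrow(cohort), 26 * 15)
  checked <- validate_mendelian(cohort)
  expect_true(all(checked$mendelian_ok))

  # every child haplotype is traceable to a parental haplotype
  for (i in seq_len(nrow(cohort))) {
    ch <- strsplit(cohort$child[i], "-", fixed = TRUE)[[1]]
    parental <- unlist(strsplit(c(cohort$mother[i], cohort$father[i]),
                                "-", fixed = TRUE))
    expect_true(all(ch %in% parental))
  }

  set.seed(77); a <- generate_cohort(synth_frequencies(panel), 5)
  set.seed(77); b <- generate_cohort(synth_frequencies(panel), 5)
  expect_identical(a, b)
})

test_that("a monomorphic panel yields no informative markers", {
  # degenerate single-haplotype frequencies: everyone is identical
  mono <- purrr::map_dfr(seq_len(nrow(panel)), function(i) {
    a <- strsplit(panel$snp1_alleles[i], "/", fixed = TRUE)[[1]][1]
    b <- strsplit(panel$snp2_alleles[i], "/", fixed = TRUE)[[1]][1]
    tibble::tibble(locus_id = panel$locus_id[i],
                   haplotype = paste0(a, b), freq = 1)
  })
  cohort <- generate_cohort(mono, n_families = 1)
  calls <- classify_trio(cohort, panel)
  expect_equal(count_informative(calls)$expected_count, 0L)
})

test_that("the zero-informative family flag produces an expected count of 0", {
  set.seed(12)
  cohort <- generate_cohort(synth_frequencies(panel), 26,
                            force_zero_family = TRUE)
  counts <- count_informative(classify_trio(cohort, panel))
  expect_equal(counts$expected_count[counts$family_id == "24"], 0L)
  expect_true(all(validate_mendelian(cohort)$mendelian_ok))
})

test_that("mean informative count per family converges to sum p(1-p)", {
  set.seed(123)
  # fixed biallelic frequencies on a 3-locus subpanel keep this cheap
  sub <- validate_panel(as.data.frame(panel[1:3, ]))
  p <- c(0.3, 0.4, 0.5)
  freqs <- purrr::map2_dfr(sub$locus_id, p, function(lid, pi) {
    row <- sub[sub$locus_id == lid, ]
    a <- strsplit(row$snp1_alleles, "/", fixed = TRUE)[[1]]
    b <- strsplit(row$snp2_alleles, "/", fixed = TRUE)[[1]]
    tibble::tibble(locus_id = lid,
                   haplotype = paste0(a, b),
                   freq = c(pi, 1 - pi))
  })
  n_fam <- 10000
  cohort <- generate_cohort(freqs, n_fam)
  # vectorised informativeness: mother SNP1-homozygous and the child
  # carrying an allele she lacks (the classifier itself is pinned to
  # this definition by the exhaustive enumeration test)
  m_gt <- snp1_genotype(cohort$mother)
  c_gt <- snp1_genotype(cohort$child)
  informative <- substr(m_gt, 1, 1) == substr(m_gt, 3, 3) & c_gt != m_gt
  counts <- tapply(informative, cohort$family_id, sum)
  expected_mean <- sum(p * (1 - p))
  per_locus_var <- sum(p * (1 - p) * (1 - p * (1 - p)))
  se <- sqrt(per_locus_var / n_fam)
  expect_lt(abs(mean(counts) - expected_mean), 3 * se)
  expect_true(all(counts >= 0 & counts <= 3))

  # and the classifier agrees with the vectorised shortcut on a slice
  slice <- cohort[cohort$family_id %in% as.character(1:50), ]
  calls <- classify_trio(slice, sub)
  key <- paste(slice$family_id, slice$locus_id)
  expect_equal(calls$informative[match(key, paste(calls$family_id,
                                                  calls$locus_id))],
               unname(informative[match(key, paste(cohort$family_id,
                                                   cohort$locus_id))]))
})

test_that("plasma samples honour concentration and fetal-fraction ranges", {
  set.seed(4)
  cohort <- generate_cohort(synth_frequencies(panel), 26)
  plasma <- generate_plasma(cohort)
  expect_equal(nrow(plasma), 26)
  expect_true(all(plasma$cfdna_conc_ng_per_ul >= 0.156 &
                    plasma$cfdna_conc_ng_per_ul <= 1.43))
  expect_true(all(plasma$fetal_fraction >= 0.05 &
                    plasma$fetal_fraction <= 0.20))

  # theoretical cffDNA concentration bounds from the default ranges
  expect_equal(0.05 * 0.156, 0.0078)
  expect_true(all(plasma$fetal_fraction * plasma$cfdna_conc_ng_per_ul >=
                    0.0078 - 1e-12))
  expect_true(all(plasma$fetal_fraction * plasma$cfdna_conc_ng_per_ul <=
                    0.20 * 1.43 + 1e-12))

  point <- generate_plasma(cohort, ff_range = c(0.10, 0.10))
  expect_true(all(point$fetal_fraction == 0.10))

  replay <- generate_plasma(cohort, conc = "table1")
  tab <- load_family_counts()
  quantified <- !is.na(tab$cfdna_conc_ng_per_ul)
  expect_equal(replay$cfdna_conc_ng_per_ul[quantified],
               tab$cfdna_conc_ng_per_ul[quantified])
})

test_that("cohorts round-trip through plain-text files", {
  set.seed(9)
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(synth_frequencies(panel), 4)
  plasma <- generate_plasma(cohort)
  files <- cohort_to_files(cohort, plasma, dir)
  expect_true(all(file.exists(files)))
  back <- read_cohort(dir)
  expect_equal(as.data.frame(back$cohort),
               as.data.frame(cohort[c("family_id", "locus_id", "mother",
                                      "father", "child")]))
  expect_equal(back$plasma$cfdna_conc_ng_per_ul,
               plasma$cfdna_conc_ng_per_ul)
  expect_equal(as.data.frame(back$panel), as.data.frame(panel))

  # empty cohort still writes loadable headers
  dir2 <- withr::local_tempdir()
  cohort_to_files(cohort[0, ], plasma[0, ], dir2)
  back2 <- read_cohort(dir2)
  expect_equal(nrow(back2$cohort), 0)
})
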