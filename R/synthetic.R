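# Synthetic study generator: haplotype frequencies, Hardy-Weinberg trio
# cohorts, and plasma cfDNA samples with a fetal fraction — everything
# needed to exercise the pipeline without real specimens.

#' Synthetic haplotype frequencies for a panel
#'
#' Each locus is biallelic at both SNPs.  SNP1 and SNP2 minor-allele
#' frequencies are drawn uniformly from `maf_range` (default 0.3-0.5,
#' the high-polymorphism regime a forensic panel is designed for) and
#' the four haplotype frequencies are assembled with strong linkage
#' disequilibrium (`dprime` of the maximal D by default 0.8), since a
#' microhaplotype's two SNPs sit within one short amplicon.
#'
#' @param panel A `snpsnp_panel` tibble.
#' @param maf_range Range of minor-allele frequencies (default
#'   `c(0.3, 0.5)`).
#' @param dprime Standardised LD coefficient D' in `[0, 1]` (default
#'   0.8).
#' @return A haplotype-frequency tibble (`locus_id`, `haplotype`,
#'   `freq`).
#' @export
synth_frequencies <- function(panel, maf_range = c(0.3, 0.5), dprime = 0.8) {
  stopifnot(length(maf_range) == 2, all(maf_range > 0), all(maf_range < 1),
            dprime >= 0, dprime <= 1)
  purrr::map_dfr(seq_len(nrow(panel)), function(i) {
    row <- panel[i, ]
    a1 <- strsplit(row$snp1_alleles, "/", fixed = TRUE)[[1]]
    a2 <- strsplit(row$snp2_alleles, "/", fixed = TRUE)[[1]]
    p <- stats::runif(1, maf_range[1], maf_range[2])  # freq of a1[1]
    q <- stats::runif(1, maf_range[1], maf_range[2])  # freq of a2[1]
    d_max <- min(p * (1 - q), (1 - p) * q)
    d <- dprime * d_max
    freq <- c(p * q + d, p * (1 - q) - d, (1 - p) * q - d,
              (1 - p) * (1 - q) + d)
    tibble::tibble(
      locus_id = row$locus_id,
      haplotype = c(paste0(a1[1], a2[1]), paste0(a1[1], a2[2]),
                    paste0(a1[2], a2[1]), paste0(a1[2], a2[2])),
      freq = freq
    )
  })
}

#' Generate a trio cohort under HWE and Mendelian transmission
#'
#' Parents are sampled from the haplotype frequencies; each child
#' receives one uniformly chosen haplotype from each parent.  Every
#' record therefore passes Mendelian validation by construction.
#'
#' @param freqs A haplotype-frequency tibble.
#' @param n_families Number of families (default 26).
#' @param force_zero_family Replace one family (the 24th when present,
#'   else the last) by a self-trio (father = mother, child = mother),
#'   which has expected informative count 0 at every locus — mirrors a
#'   cohort containing a family with no usable marker.
#' @return A tibble with `family_id`, `locus_id`, `mother`, `father`,
#'   `child`.
#' @export
generate_cohort <- function(freqs, n_families = 26,
                            force_zero_family = FALSE) {
  validate_frequencies(freqs)
  if (n_families < 1) abort_validation("n_families must be >= 1")
  fam_ids <- as.character(seq_len(n_families))
  by_locus <- split(freqs, freqs$locus_id)
  cohort <- purrr::map_dfr(by_locus, function(lf) {
    n <- n_families
    m1 <- sample(lf$haplotype, n, TRUE, lf$freq)
    m2 <- sample(lf$haplotype, n, TRUE, lf$freq)
    f1 <- sample(lf$haplotype, n, TRUE, lf$freq)
    f2 <- sample(lf$haplotype, n, TRUE, lf$freq)
    from_mother <- ifelse(stats::runif(n) < 0.5, m1, m2)
    from_father <- ifelse(stats::runif(n) < 0.5, f1, f2)
    tibble::tibble(
      family_id = fam_ids,
      locus_id = lf$locus_id[1],
      mother = make_genotype(m1, m2),
      father = make_genotype(f1, f2),
      child = make_genotype(from_mother, from_father)
    )
  })
  if (force_zero_family) {
    target <- if (n_families >= 24) "24" else fam_ids[n_families]
    idx <- cohort$family_id == target
    cohort$father[idx] <- cohort$mother[idx]
    cohort$child[idx] <- cohort$mother[idx]
  }
  dplyr::arrange(cohort, as.integer(.data$family_id), .data$locus_id)
}

#' Check Mendelian consistency of a trio table
#'
#' @param cohort A trio tibble (`family_id`, `locus_id`, `mother`,
#'   `father`, `child`).
#' @return The cohort with a logical `mendelian_ok` column.
#' @export
validate_mendelian <- function(cohort) {
  check_columns(cohort, c("family_id", "locus_id", "mother", "father",
                          "child"), "trio table")
  ok <- vapply(seq_len(nrow(cohort)), function(i) {
    mh <- genotype_haplotypes(cohort$mother[i])[[1]]
    fh <- genotype_haplotypes(cohort$father[i])[[1]]
    ch <- genotype_haplotypes(cohort$child[i])[[1]]
    (ch[1] %in% mh && ch[2] %in% fh) || (ch[2] %in% mh && ch[1] %in% fh)
  }, logical(1))
  dplyr::mutate(cohort, mendelian_ok = ok)
}

#' Generate plasma cfDNA samples for a cohort
#'
#' One plasma sample per family: total cfDNA concentration uniform over
#' `conc_range` (default the quantified range 0.156-1.43 ng/uL, or the
#' verbatim per-family concentrations with `conc = "table1"`), fetal
#' fraction uniform over `ff_range` (default 5-20%).  The maternal
#' component carries the mother's genotypes, the fetal component the
#' child's; fragment lengths follow the log-normal cfDNA model.
#'
#' @param cohort A trio tibble from [generate_cohort()].
#' @param conc_range Concentration range in ng/uL.
#' @param ff_range Fetal-fraction range.
#' @param conc `"uniform"` (default) or `"table1"` to replay the bundled
#'   per-family concentrations (the one below-quantitation sample is
#'   imputed at 0.078 ng/uL, half the quantified minimum).
#' @param state cfDNA [fragmentation_state()] (default [cfdna_state()]).
#' @return A tibble with one row per family: `family_id`,
#'   `cfdna_conc_ng_per_ul`, `fetal_fraction`, `lognormal_median_bp`,
#'   `lognormal_sigma`.
#' @export
generate_plasma <- function(cohort, conc_range = c(0.156, 1.43),
                            ff_range = c(0.05, 0.20),
                            conc = c("uniform", "table1"),
                            state = cfdna_state()) {
  conc <- match.arg(conc)
  fam_ids <- unique(cohort$family_id)
  n <- length(fam_ids)
  concs <- if (conc == "uniform") {
    stats::runif(n, conc_range[1], conc_range[2])
  } else {
    tab <- load_family_counts()
    vals <- tab$cfdna_conc_ng_per_ul[match(fam_ids, tab$family_id)]
    vals[is.na(vals)] <- 0.078
    vals
  }
  tibble::tibble(
    family_id = fam_ids,
    cfdna_conc_ng_per_ul = concs,
    fetal_fraction = stats::runif(n, ff_range[1], ff_range[2]),
    lognormal_median_bp = state$median_bp,
    lognormal_sigma = state$sigma
  )
}

#' Write a cohort to plain-text files and read it back
#'
#' Writes per-role genotype CSVs (`mother_genotypes.csv`,
#' `father_genotypes.csv`, `child_genotypes.csv`, each `sample_id,
#' locus_id, genotype`), a plasma manifest CSV, and a copy of the panel
#' TSV.
#'
#' @param cohort A trio tibble.
#' @param plasma A plasma tibble from [generate_plasma()] (optional).
#' @param dir Output directory (created if needed).
#' @param panel Panel to copy alongside (default the bundled one).
#' @return Invisibly, the vector of files written.
#' @export
cohort_to_files <- function(cohort, plasma = NULL, dir,
                            panel = load_panel()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (role in c("mother", "father", "child")) {
    path <- file.path(dir, paste0(role, "_genotypes.csv"))
    out <- tibble::tibble(sample_id = cohort$family_id,
                          locus_id = cohort$locus_id,
                          genotype = cohort[[role]])
    readr::write_csv(out, path, progress = FALSE)
    files <- c(files, path)
  }
  if (!is.null(plasma)) {
    path <- file.path(dir, "plasma_manifest.csv")
    readr::write_csv(plasma, path, progress = FALSE)
    files <- c(files, path)
  }
  panel_path <- file.path(dir, "panel.tsv")
  write_panel(panel, panel_path)
  files <- c(files, panel_path)
  invisible(files)
}

#' @rdname cohort_to_files
#' @return `read_cohort()`: a list with `cohort`, `plasma` (or `NULL`)
#'   and `panel`.
#' @export
read_cohort <- function(dir) {
  roles <- c("mother", "father", "child")
  tabs <- lapply(roles, function(role) {
    readr::read_csv(file.path(dir, paste0(role, "_genotypes.csv")),
                    show_col_types = FALSE, progress = FALSE,
                    col_types = "ccc")
  })
  cohort <- tibble::tibble(
    family_id = tabs[[1]]$sample_id,
    locus_id = tabs[[1]]$locus_id,
    mother = tabs[[1]]$genotype,
    father = tabs[[2]]$genotype,
    child = tabs[[3]]$genotype
  )
  manifest <- file.path(dir, "plasma_manifest.csv")
  plasma <- if (file.exists(manifest)) {
    readr::read_csv(manifest, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(family_id = readr::col_character()))
  } else NULL
  list(cohort = cohort, plasma = plasma,
       panel = load_panel(file.path(dir, "panel.tsv")))
}
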