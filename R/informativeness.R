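# Informative-marker classification for mother/father/child trios.
#
# A locus is informative when the child's paternally inherited SNP1 allele
# is absent from the mother's SNP1 genotype — only then can an
# allele-specific primer amplify the fetal (minor) component against the
# maternal (major) background.  Three usable/unusable patterns arise:
#   TYPE1  parents are opposite SNP1 homozygotes; whichever allele the
#          father transmits, it is absent from the mother.
#   TYPE2  mother SNP1-homozygous, father heterozygous, and the
#          transmitted paternal allele is the one the mother lacks.
#   TYPE3  as TYPE2 but the transmitted allele is shared with the mother;
#          the fetal DNA cannot be recognised.
# A SNP1-heterozygous mother (MATERNAL_HET) is never usable, and parents
# homozygous for the same allele (UNINFORMATIVE) offer nothing to target.

informativeness_levels <- c("TYPE1", "TYPE2", "TYPE3",
                            "MATERNAL_HET", "UNINFORMATIVE")

#' Attribute the child's paternal haplotype
#'
#' Given the mother's and child's haplotype-pair genotypes, returns the
#' child haplotype attributed to the father.  When both child haplotypes
#' are compatible with the mother the attribution is ambiguous and
#' flagged; when neither is, inheritance is Mendelian-impossible and an
#' error is raised.
#'
#' @param mother,child Genotype strings (`"CA-TG"` notation).
#' @return A one-row tibble with `paternal_haplotype` (`NA` when
#'   ambiguous), `ambiguous`, and a list-column `candidates` of the
#'   possible paternal haplotypes.
#' @examples
#' paternal_allele("CA-CA", "CA-TG")  # paternal "TG"
#' paternal_allele("CA-TG", "CA-TG")  # ambiguous
#' @export
paternal_allele <- function(mother, child) {
  mh <- genotype_haplotypes(mother)[[1]]
  ch <- genotype_haplotypes(child)[[1]]
  maternal_compatible <- ch %in% mh
  if (!any(maternal_compatible)) {
    abort_mendelian(sprintf(
      "child %s shares no haplotype with mother %s", child, mother))
  }
  if (all(maternal_compatible)) {
    # either child haplotype could be the paternal one
    cands <- unique(ch)
    return(tibble::tibble(paternal_haplotype = NA_character_,
                          ambiguous = TRUE, candidates = list(cands)))
  }
  pat <- ch[!maternal_compatible]
  tibble::tibble(paternal_haplotype = pat, ambiguous = FALSE,
                 candidates = list(pat))
}

#' Classify one locus of a trio
#'
#' @param mother,father,child Genotype strings for one locus.
#' @param locus Optional one-row panel tibble for the locus; when given,
#'   genotypes are validated against its declared alleles and the
#'   informative allele is matched to the allele-specific primer that
#'   targets it.
#' @return A one-row tibble: `locus_id`, `category` (factor over TYPE1,
#'   TYPE2, TYPE3, MATERNAL_HET, UNINFORMATIVE), `informative`,
#'   `informative_allele`, `informative_haplotype` (the full paternal
#'   haplotype, for simulating the SBE readout), `primer_id`.
#' @examples
#' classify_locus("CA-CA", "TG-TG", "CA-TG")  # TYPE1, allele T
#' classify_locus("CA-CA", "CA-TG", "CA-TG")  # TYPE2, allele T
#' classify_locus("CA-CA", "CA-TG", "CA-CA")  # TYPE3
#' @export
classify_locus <- function(mother, father, child, locus = NULL) {
  if (!is.null(locus)) {
    validate_genotype(c(mother, father, child), locus)
  }
  ma <- snp1_alleles_of(mother)[[1]]
  fa <- snp1_alleles_of(father)[[1]]
  ca <- snp1_alleles_of(child)[[1]]

  # Mendelian check on full haplotypes: some pairing assigns one child
  # haplotype to each parent.
  mh <- genotype_haplotypes(mother)[[1]]
  fh <- genotype_haplotypes(father)[[1]]
  ch <- genotype_haplotypes(child)[[1]]
  consistent <- (ch[1] %in% mh && ch[2] %in% fh) ||
    (ch[2] %in% mh && ch[1] %in% fh)
  if (!consistent) {
    abort_mendelian(sprintf(
      "child %s is not Mendelian-consistent with mother %s and father %s%s",
      child, mother, father,
      if (is.null(locus)) "" else sprintf(" at %s", locus$locus_id)))
  }

  locus_id <- if (is.null(locus)) NA_character_ else locus$locus_id
  mother_hom <- ma[1] == ma[2]
  father_hom <- fa[1] == fa[2]

  category <- NULL
  informative_allele <- NA_character_
  informative_haplotype <- NA_character_

  if (!mother_hom) {
    category <- "MATERNAL_HET"
  } else if (father_hom && fa[1] == ma[1]) {
    category <- "UNINFORMATIVE"
  } else if (father_hom) {
    # opposite homozygotes: the child is necessarily SNP1-het and the
    # paternal haplotype carries the non-maternal allele
    category <- "TYPE1"
    informative_allele <- fa[1]
    pat <- paternal_allele(mother, child)
    informative_haplotype <- pat$paternal_haplotype
    if (pat$ambiguous) {
      # cannot happen for valid data: a TYPE1 child haplotype carrying
      # the paternal allele is never maternal-compatible
      informative_haplotype <- pat$candidates[[1]][1]
    }
  } else {
    # mother homozygous, father heterozygous: the transmitted allele is
    # read off the child's SNP1 genotype (unambiguous because any child
    # haplotype carrying the non-maternal allele cannot be maternal)
    paternal_snp1 <- if (all(ca == ma[1])) ma[1] else setdiff(ca, ma)
    if (length(paternal_snp1) != 1) {
      abort_mendelian(sprintf(
        "child %s incompatible with homozygous mother %s", child, mother))
    }
    if (paternal_snp1 %in% ma) {
      category <- "TYPE3"
    } else {
      category <- "TYPE2"
      informative_allele <- paternal_snp1
      pat <- paternal_allele(mother, child)
      informative_haplotype <- pat$paternal_haplotype
    }
  }

  primer_id <- NA_character_
  if (!is.null(locus) && !is.na(informative_allele)) {
    primers <- panel_primers(locus)
    hit <- primers$primer_id[primers$target_snp1_allele == informative_allele]
    if (length(hit) == 1) primer_id <- hit
  }

  tibble::tibble(
    locus_id = locus_id,
    category = factor(category, levels = informativeness_levels),
    informative = category %in% c("TYPE1", "TYPE2"),
    informative_allele = informative_allele,
    informative_haplotype = informative_haplotype,
    primer_id = primer_id
  )
}

#' Classify every locus of a trio genotype table
#'
#' @param data A tibble with one row per family and locus: columns
#'   `family_id`, `locus_id`, `mother`, `father`, `child` (genotype
#'   strings).
#' @param panel A `snpsnp_panel` tibble; every panel locus must be
#'   present for every family.
#' @return A tibble of per-locus calls (one row per family x locus) with
#'   the columns of [classify_locus()] plus `family_id`.
#' @export
classify_trio <- function(data, panel) {
  check_columns(data, c("family_id", "locus_id", "mother", "father", "child"),
                "trio genotype table")
  by_family <- split(data, data$family_id)
  purrr::map_dfr(by_family, function(fam) {
    missing <- setdiff(panel$locus_id, fam$locus_id)
    if (length(missing) > 0) {
      abort_validation(sprintf(
        "family %s lacks genotypes for locus/loci: %s",
        fam$family_id[1], paste(missing, collapse = ", ")))
    }
    fam <- fam[match(panel$locus_id, fam$locus_id), ]
    purrr::map_dfr(seq_len(nrow(fam)), function(i) {
      call <- classify_locus(fam$mother[i], fam$father[i], fam$child[i],
                             locus = panel[panel$locus_id == fam$locus_id[i], ])
      dplyr::mutate(call, family_id = fam$family_id[1], .before = 1)
    })
  })
}

#' Expected informative-marker count per family
#'
#' Counts TYPE1/TYPE2 calls per family — the "expected number of
#' informative markers" that reference trio genotyping predicts before
#' any plasma reaction is run.
#'
#' @param calls Output of [classify_trio()].
#' @return A tibble with `family_id` and `expected_count`.
#' @export
count_informative <- function(calls) {
  check_columns(calls, c("family_id", "informative"), "call table")
  calls |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(expected_count = sum(.data$informative),
                     .groups = "drop")
}
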