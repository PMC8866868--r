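# The SNP-SNP marker panel: 15 microhaplotype loci, each a pair of tightly
# linked biallelic SNPs genotyped by allele-specific ARMS-PCR (targeting
# SNP1) followed by single-base extension (reading SNP2), sized on a
# capillary-electrophoresis platform.

panel_cols <- c(
  "locus_id", "snp1_alleles", "snp2_alleles",
  "arms_amplicon_bp", "sbe_amplicon_bp",
  "f1_target", "f1_lod_ng", "f1_observed_bp",
  "f2_target", "f2_lod_ng", "f2_observed_bp"
)

#' Load a SNP-SNP panel definition
#'
#' Reads a tab-separated panel table (one row per locus; `#` comments
#' allowed) and validates it: distinct single-nucleotide alleles at each
#' SNP, two allele-specific primers per locus targeting the two distinct
#' SNP1 alleles, and CE-observed SBE product sizes no smaller than the
#' designed SBE amplicon.
#'
#' @param path Path to a panel TSV. Defaults to the bundled 15-locus
#'   panel.
#' @return A tibble of class `snpsnp_panel`, one row per locus.
#' @examples
#' panel <- load_panel()
#' nrow(panel)  # 15
#' @export
load_panel <- function(path = default_panel_path()) {
  if (!file.exists(path)) {
    abort_format(sprintf("panel file does not exist: %s", path))
  }
  panel <- tryCatch(
    suppressWarnings(
    readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                    progress = FALSE,
                    col_types = readr::cols(
                      locus_id = readr::col_character(),
                      snp1_alleles = readr::col_character(),
                      snp2_alleles = readr::col_character(),
                      arms_amplicon_bp = readr::col_integer(),
                      sbe_amplicon_bp = readr::col_integer(),
                      f1_target = readr::col_character(),
                      f1_lod_ng = readr::col_double(),
                      f1_observed_bp = readr::col_integer(),
                      f2_target = readr::col_character(),
                      f2_lod_ng = readr::col_double(),
                      f2_observed_bp = readr::col_integer()
                    ))),
    error = function(e) abort_format(sprintf(
      "malformed panel file %s: %s", path, conditionMessage(e)))
  )
  if (nrow(panel) == 0 || !all(panel_cols %in% names(panel))) {
    abort_format(sprintf(
      "panel file %s is empty or lacks the panel columns", path))
  }
  validate_panel(panel)
}

#' @rdname load_panel
#' @export
default_panel_path <- function() {
  system.file("extdata", "snpsnp_panel.tsv", package = "snpsnpmix",
              mustWork = TRUE)
}

#' Validate and class a panel tibble
#'
#' @param panel A data frame with the panel columns.
#' @return The validated panel as a `snpsnp_panel` tibble.
#' @export
validate_panel <- function(panel) {
  check_columns(panel, panel_cols, "panel")
  panel <- tibble::as_tibble(panel)
  if (anyNA(panel)) {
    bad <- which(apply(is.na(panel), 1, any))
    abort_format(sprintf("panel row(s) %s contain missing fields",
                         paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(panel$locus_id)) {
    abort_validation(sprintf(
      "duplicate locus_id(s): %s",
      paste(unique(panel$locus_id[duplicated(panel$locus_id)]),
            collapse = ", ")))
  }
  for (i in seq_len(nrow(panel))) {
    row <- panel[i, ]
    for (col in c("snp1_alleles", "snp2_alleles")) {
      alleles <- strsplit(row[[col]], "/", fixed = TRUE)[[1]]
      if (length(alleles) != 2 || alleles[1] == alleles[2] ||
          !all(alleles %in% dna_bases)) {
        abort_validation(sprintf(
          "locus %s (row %d): %s must be two distinct bases like \"C/T\", got \"%s\"",
          row$locus_id, i, col, row[[col]]))
      }
    }
    snp1 <- strsplit(row$snp1_alleles, "/", fixed = TRUE)[[1]]
    if (!setequal(c(row$f1_target, row$f2_target), snp1)) {
      abort_validation(sprintf(
        "locus %s: primers must target the two distinct SNP1 alleles (%s), got F1=%s F2=%s",
        row$locus_id, row$snp1_alleles, row$f1_target, row$f2_target))
    }
    if (row$f1_observed_bp < row$sbe_amplicon_bp ||
        row$f2_observed_bp < row$sbe_amplicon_bp) {
      abort_validation(sprintf(
        "locus %s: CE-observed size below designed SBE amplicon length",
        row$locus_id))
    }
    if (row$arms_amplicon_bp <= 0 || row$sbe_amplicon_bp <= 0) {
      abort_validation(sprintf(
        "locus %s: amplicon lengths must be positive", row$locus_id))
    }
  }
  class(panel) <- c("snpsnp_panel", class(panel))
  panel
}

#' Write a panel back to TSV
#'
#' Round-trips losslessly through [load_panel()] (comments excepted).
#'
#' @param panel A `snpsnp_panel` tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_panel <- function(panel, path) {
  readr::write_tsv(panel[panel_cols], path, progress = FALSE)
  invisible(path)
}

#' Long per-primer view of a panel
#'
#' Unpivots the two allele-specific primers per locus into one row per
#' primer with ids like `"MH9-F2"`.
#'
#' @param panel A `snpsnp_panel` tibble.
#' @return A tibble with columns `primer_id`, `locus_id`, `primer`,
#'   `target_snp1_allele`, `lod_ng`, `observed_size_bp`,
#'   `arms_amplicon_bp`, `sbe_amplicon_bp`.
#' @export
panel_primers <- function(panel) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(panel),
    cols = dplyr::starts_with(c("f1_", "f2_")),
    names_to = c("primer", ".value"),
    names_pattern = "(f[12])_(.*)"
  )
  long |>
    dplyr::mutate(
      primer = toupper(.data$primer),
      primer_id = paste0(.data$locus_id, "-", .data$primer)
    ) |>
    dplyr::select("primer_id", "locus_id", "primer",
                  target_snp1_allele = "target", "lod_ng",
                  observed_size_bp = "observed_bp",
                  "arms_amplicon_bp", "sbe_amplicon_bp")
}

#' Panel amplicon-size summary
#'
#' Summarises ARMS amplicon sizes over primer rows and SBE amplicon sizes
#' over the distinct per-locus values (each locus's two primers share one
#' designed SBE amplicon, so the per-locus mean is the meaningful one).
#' Reported means are rounded half-up to whole bp.
#'
#' @param panel A `snpsnp_panel` tibble.
#' @param primer_ids Optional character vector restricting the primer rows
#'   summarised (e.g. the subset of primers actually used in a study).
#' @return A one-row tibble with `n_loci`, `n_primers`, `arms_mean_bp`,
#'   `arms_min_bp`, `arms_max_bp`, `sbe_mean_bp`, `sbe_min_bp`,
#'   `sbe_max_bp`, `observed_mean_bp`.
#' @examples
#' panel_size_summary(load_panel())
#' @export
panel_size_summary <- function(panel, primer_ids = NULL) {
  if (nrow(panel) == 0) {
    abort_validation("cannot summarise an empty panel")
  }
  primers <- panel_primers(panel)
  if (!is.null(primer_ids)) {
    unknown <- setdiff(primer_ids, primers$primer_id)
    if (length(unknown) > 0) {
      abort_validation(sprintf("unknown primer_id(s): %s",
                               paste(unknown, collapse = ", ")))
    }
    primers <- dplyr::filter(primers, .data$primer_id %in% primer_ids)
  }
  per_locus_sbe <- primers |>
    dplyr::distinct(.data$locus_id, .data$sbe_amplicon_bp)
  tibble::tibble(
    n_loci = dplyr::n_distinct(primers$locus_id),
    n_primers = nrow(primers),
    arms_mean_bp = round_half_up(mean(primers$arms_amplicon_bp)),
    arms_min_bp = min(primers$arms_amplicon_bp),
    arms_max_bp = max(primers$arms_amplicon_bp),
    sbe_mean_bp = round_half_up(mean(per_locus_sbe$sbe_amplicon_bp)),
    sbe_min_bp = min(per_locus_sbe$sbe_amplicon_bp),
    sbe_max_bp = max(per_locus_sbe$sbe_amplicon_bp),
    observed_mean_bp = round_half_up(mean(primers$observed_size_bp))
  )
}

#' Bundled per-primer plasma usage report
#'
#' The 26 informative-marker primers actually applied to the plasma
#' cohort, with successful/total single-reaction tallies, amplicon
#' geometry and CE-observed cffDNA product sizes.
#'
#' @return A tibble with columns `primer_id`, `successful`, `total`,
#'   `rate`, `arms_amplicon_bp`, `sbe_amplicon_bp`, `observed_size_bp`.
#' @export
load_primer_report <- function() {
  path <- system.file("extdata", "informative_primer_report.tsv",
                      package = "snpsnpmix", mustWork = TRUE)
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE) |>
    dplyr::mutate(rate = .data$successful / .data$total,
                  .after = "total")
}

#' Bundled per-family cfDNA accounting table
#'
#' Extracted cfDNA concentration and expected/observed informative-marker
#' counts for the 26-family plasma cohort.  The one sample whose
#' concentration fell below the assay's quantitation range is stored as
#' `NA`.
#'
#' @return A tibble with columns `family_id`, `cfdna_conc_ng_per_ul`,
#'   `expected_count`, `observed_count`.
#' @export
load_family_counts <- function() {
  path <- system.file("extdata", "table1_counts.csv",
                      package = "snpsnpmix", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = "cdii")
}
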