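# End-to-end noninvasive prenatal analysis: pick informative markers from
# reference trio genotypes, run one simulated allele-specific single
# reaction per marker on the plasma mixture, and account for
# expected/observed informative markers per family and across the
# cohort.

#' Run the plasma stage for one family
#'
#' Classifies the family's reference genotypes, then simulates one
#' single-primer cfDNA reaction per informative marker: total template
#' is `cfdna_conc_ng_per_ul` x `input_ul`, split into a maternal
#' component (mother's genotypes, mass `(1 - ff) x total`) and a fetal
#' component (child's genotypes, `ff x total`), each thinned by the
#' amplicon's survival under the cfDNA fragment-length model, with the
#' 32-cycle protocol boost applied.
#'
#' @param trio One family's rows of a trio tibble (`family_id`,
#'   `locus_id`, `mother`, `father`, `child`).
#' @param plasma One row of a plasma tibble ([generate_plasma()]).
#' @param panel A `snpsnp_panel` tibble.
#' @param params An [amplification_params()] list.
#' @param deterministic Disable peak noise?
#' @param input_ul Template volume per reaction (default 1 uL).
#' @return A `family_report` tibble: one row per informative marker with
#'   `family_id`, `locus_id`, `primer_id`, `category`,
#'   `observed_size_bp`, `height_rfu`, `detected`; attributes
#'   `expected_count`, `observed_count`.  A family with no informative
#'   marker yields zero rows (expected 0), not an error.
#' @export
run_family <- function(trio, plasma, panel,
                       params = amplification_params(),
                       deterministic = FALSE, input_ul = 1) {
  stopifnot(nrow(plasma) == 1)
  calls <- classify_trio(trio, panel)
  informative <- dplyr::filter(calls, .data$informative)
  primers <- panel_primers(panel)
  state <- fragmentation_state("lognormal",
                               median_bp = plasma$lognormal_median_bp,
                               sigma = plasma$lognormal_sigma)
  total_ng <- plasma$cfdna_conc_ng_per_ul * input_ul
  ff <- plasma$fetal_fraction

  rows <- purrr::map_dfr(seq_len(nrow(informative)), function(i) {
    call <- informative[i, ]
    primer <- primers[primers$primer_id == call$primer_id, ]
    fam <- trio[trio$locus_id == call$locus_id, ]
    survival <- amplicon_survival(primer$arms_amplicon_bp, state)
    mix <- tibble::tibble(
      genotype = c(fam$mother, fam$child),
      mass_ng = c((1 - ff) * total_ng, ff * total_ng) * survival
    )
    peak <- simulate_peak(primer, mix, params,
                          deterministic = deterministic, cfdna = TRUE,
                          sample_id = trio$family_id[1])
    tibble::tibble(
      family_id = trio$family_id[1],
      locus_id = call$locus_id,
      primer_id = call$primer_id,
      category = call$category,
      observed_size_bp = peak$observed_size_bp,
      height_rfu = peak$height_rfu,
      detected = peak$detected
    )
  })
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(
      family_id = character(0), locus_id = character(0),
      primer_id = character(0),
      category = factor(character(0), levels = informativeness_levels),
      observed_size_bp = integer(0), height_rfu = numeric(0),
      detected = logical(0)
    )
  }
  structure(rows, expected_count = nrow(informative),
            observed_count = sum(rows$detected),
            class = c("family_report", class(rows)))
}

#' Run the plasma stage for a whole cohort
#'
#' @param cohort A trio tibble covering one or more families.
#' @param plasma A plasma tibble with one row per family.
#' @param panel A `snpsnp_panel` tibble.
#' @inheritParams run_family
#' @return A list of class `plasma_run` with `outcomes` (all per-primer
#'   rows) and `families` (per-family `family_id`,
#'   `cfdna_conc_ng_per_ul`, `expected_count`, `observed_count`).
#' @export
run_cohort <- function(cohort, plasma, panel,
                       params = amplification_params(),
                       deterministic = FALSE, input_ul = 1) {
  fam_ids <- unique(cohort$family_id)
  reports <- lapply(fam_ids, function(fid) {
    run_family(cohort[cohort$family_id == fid, ],
               plasma[plasma$family_id == fid, ], panel,
               params = params, deterministic = deterministic,
               input_ul = input_ul)
  })
  families <- tibble::tibble(
    family_id = fam_ids,
    cfdna_conc_ng_per_ul =
      plasma$cfdna_conc_ng_per_ul[match(fam_ids, plasma$family_id)],
    expected_count = vapply(reports, attr, integer(1), "expected_count",
                            exact = TRUE),
    observed_count = vapply(reports, function(r)
      as.integer(attr(r, "observed_count")), integer(1))
  )
  structure(list(outcomes = dplyr::bind_rows(reports), families = families),
            class = "plasma_run")
}

#' Summarise a cohort's expected/observed accounting
#'
#' Works either on a `plasma_run` (simulated) or directly on a
#' family-level tibble with `expected_count` and `observed_count`
#' columns, such as the bundled accounting table from
#' [load_family_counts()].  The detection rate is
#' `100 x total_observed / total_expected`, one decimal, half-up.
#'
#' @param x A `plasma_run` or a family-count tibble.
#' @return A list of class `cohort_summary`: `families`, `outcomes`
#'   (when available), `total_expected`, `total_observed`,
#'   `detection_rate_percent` (`NA` when nothing was expected), and
#'   `size_range_bp`/`size_mean_bp` over detected products when
#'   per-primer outcomes are available.
#' @examples
#' summarize_cohort(load_family_counts())
#' @export
summarize_cohort <- function(x) {
  outcomes <- NULL
  if (inherits(x, "plasma_run")) {
    families <- x$families
    outcomes <- x$outcomes
  } else {
    check_columns(x, c("family_id", "expected_count", "observed_count"),
                  "family-count table")
    families <- tibble::as_tibble(x)
  }
  if (nrow(families) == 0) abort_validation("no families to summarise")
  bad <- families$observed_count > families$expected_count
  if (any(bad)) {
    abort_validation(sprintf(
      "observed_count exceeds expected_count for family/families %s",
      paste(families$family_id[bad], collapse = ", ")))
  }
  total_expected <- sum(families$expected_count)
  total_observed <- sum(families$observed_count)
  rate <- if (total_expected == 0) NA_real_ else
    round_half_up(100 * total_observed / total_expected, 1)
  size_range <- size_mean <- NULL
  if (!is.null(outcomes) && any(outcomes$detected)) {
    sizes <- outcomes$observed_size_bp[outcomes$detected]
    size_range <- range(sizes)
    size_mean <- round_half_up(mean(sizes))
  }
  structure(list(families = families, outcomes = outcomes,
                 total_expected = total_expected,
                 total_observed = total_observed,
                 detection_rate_percent = rate,
                 size_range_bp = size_range, size_mean_bp = size_mean),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("SNP-SNP plasma cohort summary\n")
  cat(sprintf("  families:              %d\n", nrow(x$families)))
  cat(sprintf("  informative markers:   expected %d, observed %d\n",
              x$total_expected, x$total_observed))
  cat(sprintf("  detection rate:        %s%%\n",
              ifelse(is.na(x$detection_rate_percent), "n/a",
                     format(x$detection_rate_percent))))
  if (!is.null(x$size_mean_bp)) {
    cat(sprintf("  detected product size: %d-%d bp (mean %d)\n",
                x$size_range_bp[1], x$size_range_bp[2], x$size_mean_bp))
  }
  invisible(x)
}

#' Per-primer successful/total detection tallies
#'
#' From simulated outcomes (`primer_id` + `detected` rows) or from a
#' report table that already carries `successful`/`total` columns.
#'
#' @param x A `plasma_run`, an outcome tibble, or a successful/total
#'   report such as [load_primer_report()].
#' @return A tibble with `primer_id`, `successful`, `total`, `rate`.
#' @export
primer_detection_rates <- function(x) {
  if (inherits(x, "plasma_run")) x <- x$outcomes
  if (all(c("successful", "total") %in% names(x))) {
    return(dplyr::mutate(
      dplyr::select(tibble::as_tibble(x), "primer_id", "successful", "total"),
      rate = .data$successful / .data$total))
  }
  check_columns(x, c("primer_id", "detected"), "outcome table")
  x |>
    dplyr::group_by(.data$primer_id) |>
    dplyr::summarise(successful = sum(.data$detected),
                     total = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(rate = .data$successful / .data$total)
}

#' Concentration vs detection association
#'
#' Spearman rank correlation between total cfDNA concentration and the
#' per-family detected fraction (observed/expected), over families with
#' at least one informative marker.  Descriptive only — no test
#' statistic is attached, matching the qualitative nature of the claim
#' it probes.
#'
#' @param x A `cohort_summary`, `plasma_run`, or family-count tibble
#'   with a `cfdna_conc_ng_per_ul` column.
#' @return A one-row tibble: `n_families`, `spearman_rho` (`NA` with
#'   `zero_variance = TRUE` when every family detects everything or the
#'   fractions are constant), `zero_variance`.
#' @export
correlation_report <- function(x) {
  if (inherits(x, "cohort_summary")) x <- x$families
  if (inherits(x, "plasma_run")) x <- x$families
  check_columns(x, c("cfdna_conc_ng_per_ul", "expected_count",
                     "observed_count"), "family table")
  fams <- x |>
    dplyr::filter(.data$expected_count > 0,
                  !is.na(.data$cfdna_conc_ng_per_ul)) |>
    dplyr::mutate(fraction = .data$observed_count / .data$expected_count)
  if (nrow(fams) < 3) {
    abort_validation(sprintf(
      "need at least 3 quantified families with informative markers, got %d",
      nrow(fams)))
  }
  zero_var <- stats::sd(fams$fraction) == 0 ||
    stats::sd(fams$cfdna_conc_ng_per_ul) == 0
  rho <- if (zero_var) NA_real_ else
    stats::cor(fams$cfdna_conc_ng_per_ul, fams$fraction,
               method = "spearman")
  tibble::tibble(n_families = nrow(fams), spearman_rho = rho,
                 zero_variance = zero_var)
}
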