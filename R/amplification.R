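# Allele-specific ARMS-PCR + SBE readout simulator.
#
# The peak-height law is a deliberately simple surrogate for the CE
# trace: expected height is linear in the mass of template carrying the
# primer's SNP1 target allele, anchored so that a deterministic reaction
# at exactly the primer's limit-of-detection mass lands on the 50 RFU
# calling threshold.  Realised heights are log-normal around the
# expectation.  Stutter is never simulated: SNP-type markers produce
# none.

#' Amplification model parameters
#'
#' @param threshold_rfu Peak-calling threshold (default 50 RFU).
#' @param noise_cv Coefficient of variation of the log-normal peak noise
#'   (default 0.3); `deterministic = TRUE` in the simulators bypasses it.
#' @param nonspecific_rate Fraction of non-target template a primer
#'   amplifies anyway (default 1e-4, i.e. mis-priming specificity of
#'   about 1:10,000 per reaction).
#' @param cycle_boost Multiplicative gain of the 32-cycle cfDNA protocol
#'   over the standard 30-cycle one (default 4, roughly a doubling per
#'   extra cycle away from plateau); applied only when a simulator is
#'   told `cfdna = TRUE`.
#' @param efficiency_penalty Named numeric vector of per-primer
#'   multiplicative gain penalties (default none); lets a locus that
#'   underperforms in multiplex be emulated.
#' @return A list of class `amp_params`.
#' @export
amplification_params <- function(threshold_rfu = 50, noise_cv = 0.3,
                                 nonspecific_rate = 1e-4, cycle_boost = 4,
                                 efficiency_penalty = NULL) {
  stopifnot(threshold_rfu > 0, noise_cv >= 0,
            nonspecific_rate >= 0, nonspecific_rate < 1,
            cycle_boost > 0)
  structure(list(threshold_rfu = threshold_rfu, noise_cv = noise_cv,
                 nonspecific_rate = nonspecific_rate,
                 cycle_boost = cycle_boost,
                 efficiency_penalty = efficiency_penalty),
            class = "amp_params")
}

#' Template mass carrying a primer's target allele
#'
#' Each contributor donates `mass * copies / 2` ng of target template,
#' where `copies` counts haplotypes whose SNP1 base equals the primer's
#' target (0, 1 or 2).
#'
#' @param contributors A tibble with columns `genotype` and `mass_ng`
#'   (one row per contributor, genotypes at the primer's locus).
#' @param target_allele Single SNP1 base the primer targets.
#' @return Mass in ng.
#' @examples
#' mix <- tibble::tibble(genotype = c("CA-TG", "CA-CA"),
#'                       mass_ng = c(0.05, 50))
#' target_mass(mix, "T")  # 0.025: only the minor's TG haplotype
#' @export
target_mass <- function(contributors, target_allele) {
  check_columns(contributors, c("genotype", "mass_ng"), "contributor table")
  if (anyNA(contributors$genotype)) {
    abort_validation("missing genotype for a contributor")
  }
  copies <- vapply(snp1_alleles_of(contributors$genotype),
                   function(a) sum(a == target_allele), numeric(1))
  sum(contributors$mass_ng * copies / 2)
}

lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sigma <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
}

#' Expected (noise-free) peak height
#'
#' `threshold_rfu * boost * (target + nonspecific_rate * nontarget) /
#' (lod / 2)`.  A primer's published sensitivity is the smallest input
#' mass of a SNP1-heterozygous single-source sample that yields a
#' positive result, and a heterozygote carries half its mass as target
#' template — so the calibration anchor is `lod_ng / 2` ng of *target*
#' template, where the expected height equals the threshold exactly
#' under the standard protocol.  This is what lets the same primer
#' detect the heterozygous minor contributor of a 1:1,000 mixture at
#' 0.05 ng (0.025 ng of target).
#'
#' @param lod_ng Primer limit of detection (ng of heterozygous input
#'   DNA, as published).
#' @param target_ng,nontarget_ng Template masses (ng).
#' @param params An [amplification_params()] list.
#' @param cfdna Apply the 32-cycle boost?
#' @param primer_id Optional, looks up a per-primer efficiency penalty.
#' @return Expected height in RFU.
#' @export
expected_peak_height <- function(lod_ng, target_ng, nontarget_ng = 0,
                                 params = amplification_params(),
                                 cfdna = FALSE, primer_id = NULL) {
  boost <- if (cfdna) params$cycle_boost else 1
  penalty <- 1
  if (!is.null(primer_id) && !is.null(params$efficiency_penalty) &&
      primer_id %in% names(params$efficiency_penalty)) {
    penalty <- params$efficiency_penalty[[primer_id]]
  }
  params$threshold_rfu * boost * penalty *
    (target_ng + params$nonspecific_rate * nontarget_ng) / (lod_ng / 2)
}

#' Simulate one allele-specific single reaction
#'
#' @param primer One row of [panel_primers()].
#' @param contributors A tibble with `genotype` (at the primer's locus)
#'   and `mass_ng`.
#' @param params An [amplification_params()] list.
#' @param deterministic Disable peak noise?
#' @param cfdna Apply the 32-cycle cfDNA protocol boost?
#' @param sample_id Label carried into the output row.
#' @return A one-row peak-table tibble: `sample_id`, `primer_id`,
#'   `observed_size_bp`, `height_rfu`, `detected`.
#' @export
simulate_peak <- function(primer, contributors,
                          params = amplification_params(),
                          deterministic = FALSE, cfdna = FALSE,
                          sample_id = NA_character_) {
  total <- sum(contributors$mass_ng)
  tm <- target_mass(contributors, primer$target_snp1_allele)
  expected <- expected_peak_height(primer$lod_ng, tm, total - tm,
                                   params, cfdna = cfdna,
                                   primer_id = primer$primer_id)
  height <- if (deterministic) expected else
    expected * lognormal_noise(1, params$noise_cv)
  tibble::tibble(
    sample_id = sample_id,
    primer_id = primer$primer_id,
    observed_size_bp = primer$observed_size_bp,
    height_rfu = height,
    detected = height >= params$threshold_rfu
  )
}

#' Per-primer sensitivity dilution series
#'
#' Replays the single-primer sensitivity experiment: a single-source,
#' SNP1-heterozygous template is diluted over `masses` and each
#' replicate's detection outcome is recorded.  A heterozygote carries
#' half its mass as target template, so with noise off the smallest
#' detected input mass equals the primer's published LOD.
#'
#' @param primer One row of [panel_primers()].
#' @param masses Input masses in ng (default the published series).
#' @param params An [amplification_params()] list.
#' @param replicates Replicates per mass (default 100).
#' @param deterministic Disable noise (forces rate 0 or 1).
#' @return A tibble with `mass_ng`, `detection_rate`, `replicates`.
#' @export
sensitivity_assay <- function(primer, masses = c(1, 0.5, 0.1, 0.05, 0.025),
                              params = amplification_params(),
                              replicates = 100, deterministic = FALSE) {
  if (any(masses < 0)) abort_validation("input masses must be non-negative")
  purrr::map_dfr(masses, function(m) {
    expected <- expected_peak_height(primer$lod_ng, m / 2, m / 2, params)
    heights <- if (deterministic) rep(expected, replicates) else
      expected * lognormal_noise(replicates, params$noise_cv)
    tibble::tibble(mass_ng = m,
                   detection_rate = mean(heights >= params$threshold_rfu),
                   replicates = replicates)
  })
}

#' Simulate a two-person mixture dilution series
#'
#' For each locus at which the minor contributor carries a SNP1 allele
#' the major lacks, simulates the minor-specific single reaction across
#' the dilution series with the minor mass fixed.
#'
#' @param minor,major Tibbles with `locus_id` and `genotype` for the two
#'   contributors.
#' @param panel A `snpsnp_panel` tibble.
#' @param ratios Major:minor ratios (default the published series
#'   1, 10, 20, 50, 100, 500, 1000).
#' @param minor_mass_ng Minor-contributor mass (default 0.05 ng).
#' @param params An [amplification_params()] list.
#' @param deterministic Disable noise?
#' @return A peak-table tibble with `locus_id`, `primer_id`,
#'   `target_allele`, `ratio`, `ratio_label`, `observed_size_bp`,
#'   `height_rfu`, `detected`.  Empty (with a warning) when no locus is
#'   informative.
#' @export
mixture_series <- function(minor, major, panel,
                           ratios = c(1, 10, 20, 50, 100, 500, 1000),
                           minor_mass_ng = 0.05,
                           params = amplification_params(),
                           deterministic = FALSE) {
  check_columns(minor, c("locus_id", "genotype"), "minor genotype table")
  check_columns(major, c("locus_id", "genotype"), "major genotype table")
  if (minor_mass_ng <= 0 || any(ratios <= 0)) {
    abort_validation("minor mass and ratios must be positive")
  }
  primers <- panel_primers(panel)
  rows <- purrr::map_dfr(panel$locus_id, function(lid) {
    mi <- minor$genotype[minor$locus_id == lid]
    mj <- major$genotype[major$locus_id == lid]
    if (length(mi) != 1 || length(mj) != 1) return(tibble::tibble())
    informative_alleles <- setdiff(snp1_alleles_of(mi)[[1]],
                                   snp1_alleles_of(mj)[[1]])
    if (length(informative_alleles) == 0) return(tibble::tibble())
    purrr::map_dfr(unique(informative_alleles), function(allele) {
      primer <- primers[primers$locus_id == lid &
                          primers$target_snp1_allele == allele, ]
      purrr::map_dfr(ratios, function(r) {
        mix <- tibble::tibble(genotype = c(mi, mj),
                              mass_ng = c(minor_mass_ng, minor_mass_ng * r))
        peak <- simulate_peak(primer, mix, params,
                              deterministic = deterministic)
        tibble::tibble(locus_id = lid, primer_id = primer$primer_id,
                       target_allele = allele, ratio = r,
                       ratio_label = paste0("1:", format(r, scientific = FALSE,
                                                         big.mark = ",")),
                       observed_size_bp = peak$observed_size_bp,
                       height_rfu = peak$height_rfu,
                       detected = peak$detected)
      })
    })
  })
  if (nrow(rows) == 0) {
    rlang::warn("no informative locus: contributors share all SNP1 alleles")
  }
  rows
}

#' Deepest mixture ratio still detected, per locus
#'
#' @param peaks Output of [mixture_series()].
#' @return A tibble with `locus_id`, `primer_id`, `max_ratio_detected`
#'   (`NA` when never detected).
#' @export
deepest_ratio_detected <- function(peaks) {
  peaks |>
    dplyr::group_by(.data$locus_id, .data$primer_id) |>
    dplyr::summarise(
      max_ratio_detected = if (any(.data$detected))
        max(.data$ratio[.data$detected]) else NA_real_,
      .groups = "drop"
    )
}
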