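# Panel-level population genetics under Hardy-Weinberg equilibrium.
#
# Frequencies are supplied as a long tibble: one row per locus and
# haplotype with columns locus_id, haplotype, freq.  SNP1 allele
# frequencies are the marginals over the first base of each haplotype.

#' Validate a haplotype-frequency table
#'
#' @param freqs A tibble with columns `locus_id`, `haplotype`, `freq`.
#' @param tol Tolerance on per-locus frequency sums (default 1e-9).
#' @return Invisibly, `freqs`.
#' @export
validate_frequencies <- function(freqs, tol = 1e-9) {
  check_columns(freqs, c("locus_id", "haplotype", "freq"),
                "frequency table")
  if (nrow(freqs) == 0) abort_validation("empty frequency table")
  if (any(freqs$freq < 0 | freqs$freq > 1)) {
    abort_validation("haplotype frequencies must lie in [0, 1]")
  }
  sums <- tapply(freqs$freq, freqs$locus_id, sum)
  off <- abs(sums - 1) > tol
  if (any(off)) {
    abort_validation(sprintf(
      "haplotype frequencies do not sum to 1 at locus/loci: %s",
      paste(names(sums)[off], collapse = ", ")))
  }
  invisible(freqs)
}

#' SNP1 allele-frequency marginals
#'
#' @param freqs A haplotype-frequency tibble (see
#'   [validate_frequencies()]).
#' @return A tibble with `locus_id`, `allele`, `freq`.
#' @export
snp1_marginals <- function(freqs) {
  validate_frequencies(freqs)
  freqs |>
    dplyr::mutate(allele = substr(.data$haplotype, 1, 1)) |>
    dplyr::group_by(.data$locus_id, .data$allele) |>
    dplyr::summarise(freq = sum(.data$freq), .groups = "drop")
}

#' Probability that a locus is informative for a random family
#'
#' Under random mating, a locus lets an allele-specific primer pick the
#' fetal component out of maternal plasma exactly when the mother is
#' SNP1-homozygous for some allele a and the paternally transmitted SNP1
#' allele differs from a.  With HWE genotypes and the father's
#' transmitted allele an independent population draw this is
#' \deqn{\sum_a p_a^2 (1 - p_a),}
#' which reduces to \eqn{p(1-p)} for a biallelic SNP1.
#'
#' @param freqs A haplotype-frequency tibble covering one or more loci.
#' @return A tibble with `locus_id` and `p_informative`.
#' @examples
#' f <- tibble::tibble(locus_id = "L1",
#'                     haplotype = c("CA", "TG"),
#'                     freq = c(0.3, 0.7))
#' prob_informative_locus(f)  # 0.3 * 0.7 = 0.21
#' @export
prob_informative_locus <- function(freqs) {
  snp1_marginals(freqs) |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(
      p_informative = sum(.data$freq^2 * (1 - .data$freq)),
      .groups = "drop"
    )
}

#' Distribution of the panel's informative-marker count
#'
#' Treating loci as unlinked, the number of informative markers a random
#' family presents is Poisson-binomial over the per-locus probabilities;
#' computed by exact convolution.
#'
#' @param p Either a numeric vector of per-locus probabilities or a
#'   haplotype-frequency tibble (run through
#'   [prob_informative_locus()] first).
#' @return A tibble with `count` (0..L) and `prob`.
#' @examples
#' d <- panel_informative_count_distribution(rep(0.25, 15))
#' d$prob[d$count == 0]  # 0.75^15
#' @export
panel_informative_count_distribution <- function(p) {
  if (is.data.frame(p)) p <- prob_informative_locus(p)$p_informative
  if (length(p) == 0) abort_validation("no per-locus probabilities supplied")
  if (any(p < 0 | p > 1)) {
    abort_validation("per-locus probabilities must lie in [0, 1]")
  }
  mass <- 1
  for (pi in p) {
    mass <- c(mass * (1 - pi), 0) + c(0, mass * pi)
  }
  tibble::tibble(count = seq_along(mass) - 1L, prob = mass)
}

#' Effective number of alleles and expected heterozygosity
#'
#' Ae = 1 / sum(q^2) over haplotype frequencies q — the polymorphism
#' measure used to rank microhaplotype markers — together with expected
#' heterozygosity 1 - sum(q^2).
#'
#' @param freqs A haplotype-frequency tibble.
#' @return A tibble with `locus_id`, `ae`, `heterozygosity`.
#' @examples
#' f <- tibble::tibble(locus_id = "L1",
#'                     haplotype = c("CA", "CG", "TA", "TG"),
#'                     freq = rep(0.25, 4))
#' effective_allele_number(f)  # Ae = 4
#' @export
effective_allele_number <- function(freqs) {
  validate_frequencies(freqs)
  freqs |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(
      ae = 1 / sum(.data$freq^2),
      heterozygosity = 1 - sum(.data$freq^2),
      .groups = "drop"
    )
}

#' Sample Hardy-Weinberg genotypes
#'
#' Draws, for each locus and sample, two haplotypes i.i.d. from the
#' haplotype frequencies and assembles unordered genotype strings.
#'
#' @param freqs A haplotype-frequency tibble.
#' @param n Number of individuals.
#' @param sample_ids Optional ids (default `S1..Sn`).
#' @return A tibble with `sample_id`, `locus_id`, `genotype`.
#' @export
sample_hwe_genotypes <- function(freqs, n, sample_ids = NULL) {
  validate_frequencies(freqs)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  by_locus <- split(freqs, freqs$locus_id)
  purrr::map_dfr(by_locus, function(lf) {
    h1 <- sample(lf$haplotype, n, replace = TRUE, prob = lf$freq)
    h2 <- sample(lf$haplotype, n, replace = TRUE, prob = lf$freq)
    tibble::tibble(sample_id = sample_ids,
                   locus_id = lf$locus_id[1],
                   genotype = make_genotype(h1, h2))
  })
}
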