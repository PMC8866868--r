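# Fragment-length models for degraded genomic DNA and cell-free DNA, and
# the probability that an amplicon's template interval survives
# fragmentation intact.
#
# Heat degradation is modelled as a Poisson breakpoint process along the
# molecule (exponential fragment lengths); circulating cfDNA, whose
# apoptotic fragmentation concentrates around a mono-nucleosomal mode,
# is modelled log-normal with median 143 bp.

#' Describe a fragmentation state
#'
#' @param model `"exponential"` (Poisson random breaks, heat-degraded
#'   gDNA) or `"lognormal"` (cfDNA).
#' @param mean_fragment_bp Mean fragment length for the exponential
#'   model.
#' @param median_bp,sigma Log-normal parameters for the cfDNA model
#'   (defaults 143 bp and 0.30; 0.30 is the largest round sigma keeping
#'   the >300 bp tail under 1% at that median).
#' @return A list of class `fragmentation_state`.
#' @export
fragmentation_state <- function(model = c("exponential", "lognormal"),
                                mean_fragment_bp = NULL,
                                median_bp = 143, sigma = 0.30) {
  model <- match.arg(model)
  if (model == "exponential") {
    if (is.null(mean_fragment_bp) || mean_fragment_bp <= 0) {
      abort_validation("exponential model needs mean_fragment_bp > 0")
    }
  } else {
    if (median_bp <= 0 || sigma < 0) {
      abort_validation("lognormal model needs median_bp > 0 and sigma >= 0")
    }
  }
  structure(list(model = model, mean_fragment_bp = mean_fragment_bp,
                 median_bp = median_bp, sigma = sigma),
            class = "fragmentation_state")
}

#' Named heat-degradation severity presets
#'
#' Mean-fragment-length presets standing in for the incubation series
#' used on genomic DNA (98 degrees C for 35/40/45 min) and on a standard
#' DNA (120/160/170 min); the published evidence is qualitative
#' (fragments concentrated below 200 bp), so these are acknowledged
#' model choices.
#'
#' @return A named numeric vector of mean fragment lengths in bp.
#' @export
degradation_presets <- function() {
  c("gdna-35min" = 150, "gdna-40min" = 120, "gdna-45min" = 100,
    "std-120min" = 120, "std-160min" = 90, "std-170min" = 80)
}

#' @rdname degradation_presets
#' @param preset Name of a preset.
#' @export
degraded_state <- function(preset) {
  presets <- degradation_presets()
  if (!preset %in% names(presets)) {
    abort_validation(sprintf("unknown degradation preset \"%s\"; one of: %s",
                             preset, paste(names(presets), collapse = ", ")))
  }
  fragmentation_state("exponential", mean_fragment_bp = presets[[preset]])
}

#' cfDNA fragmentation state
#' @rdname fragmentation_state
#' @export
cfdna_state <- function(median_bp = 143, sigma = 0.30) {
  fragmentation_state("lognormal", median_bp = median_bp, sigma = sigma)
}

#' Probability an amplicon survives fragmentation
#'
#' Under Poisson breaks at rate `1/mean_fragment_bp` an interval of
#' length L is unbroken with probability `exp(-L/mean)`.  Under the
#' log-normal cfDNA model the surviving fraction is the probability that
#' a fragment is at least as long as the amplicon.  Length 0 is the
#' intact limit (probability 1); negative lengths error.
#'
#' @param amplicon_bp Amplicon length(s) in bp.
#' @param state A [fragmentation_state()].
#' @return Survival probabilities in `[0, 1]`.
#' @examples
#' amplicon_survival(150, fragmentation_state("exponential", 150))  # exp(-1)
#' @export
amplicon_survival <- function(amplicon_bp, state) {
  if (any(amplicon_bp < 0)) {
    abort_validation("amplicon length must be non-negative")
  }
  switch(state$model,
    exponential = exp(-amplicon_bp / state$mean_fragment_bp),
    lognormal = stats::plnorm(amplicon_bp, meanlog = log(state$median_bp),
                              sdlog = max(state$sigma, .Machine$double.eps),
                              lower.tail = FALSE)
  )
}

#' Sample cell-free DNA fragment lengths
#'
#' Log-normal draws with the state's median and sigma; with the default
#' parameters the empirical median is ~143 bp and under 1% of fragments
#' exceed 300 bp.
#'
#' @param n Number of fragments.
#' @param state A log-normal [fragmentation_state()] (default
#'   [cfdna_state()]).
#' @return Numeric vector of lengths in bp.
#' @export
sample_cffdna_length <- function(n, state = cfdna_state()) {
  if (state$model != "lognormal") {
    abort_validation("sample_cffdna_length requires a lognormal state")
  }
  if (state$sigma == 0) return(rep(state$median_bp, n))
  stats::rlnorm(n, meanlog = log(state$median_bp), sdlog = state$sigma)
}

#' Genotyping success of short vs long amplicons under degradation
#'
#' For every panel primer and every comparison STR-style amplicon,
#' combines amplicon survival with the detection model: the effective
#' template reaching the reaction is `input_ng * survival`, a
#' heterozygous single source carries half of it as target, and success
#' probability is the chance the (log-normal) peak clears the threshold.
#'
#' @param panel A `snpsnp_panel` tibble.
#' @param str_amplicons_bp Lengths of the comparison long-amplicon
#'   markers (default 250-450 bp).
#' @param state A [fragmentation_state()].
#' @param params An [amplification_params()] list.
#' @param input_ng Input DNA mass (default 1 ng).
#' @param str_lod_ng LOD granted to the comparison markers (default
#'   0.025 ng, i.e. as sensitive as the best panel primers).
#' @return A tibble with `marker_id`, `marker_class` (`"snp_snp"` /
#'   `"str"`), `amplicon_bp`, `survival`, `success_prob`.
#' @export
degraded_genotyping_comparison <- function(panel,
                                           str_amplicons_bp = seq(250, 450, 50),
                                           state,
                                           params = amplification_params(),
                                           input_ng = 1,
                                           str_lod_ng = 0.025) {
  primers <- panel_primers(panel)
  markers <- dplyr::bind_rows(
    tibble::tibble(marker_id = primers$primer_id, marker_class = "snp_snp",
                   amplicon_bp = primers$arms_amplicon_bp,
                   lod_ng = primers$lod_ng),
    tibble::tibble(marker_id = paste0("STR-", str_amplicons_bp, "bp"),
                   marker_class = "str", amplicon_bp = str_amplicons_bp,
                   lod_ng = str_lod_ng)
  )
  markers |>
    dplyr::mutate(
      survival = amplicon_survival(.data$amplicon_bp, state),
      expected_height = expected_peak_height(
        .data$lod_ng, input_ng * .data$survival / 2,
        input_ng * .data$survival / 2, params),
      success_prob = detection_probability(.data$expected_height, params)
    ) |>
    dplyr::select(-"lod_ng", -"expected_height")
}

# P(log-normal peak with given expectation clears the threshold)
detection_probability <- function(expected_height, params) {
  if (params$noise_cv <= 0) {
    return(as.numeric(expected_height >= params$threshold_rfu))
  }
  sigma <- sqrt(log1p(params$noise_cv^2))
  stats::plnorm(params$threshold_rfu / pmax(expected_height, 1e-300),
                meanlog = -sigma^2 / 2, sdlog = sigma, lower.tail = FALSE)
}
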