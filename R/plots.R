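# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Expected vs observed informative markers per family
#'
#' Side-by-side bars per family, the standard way such cohorts are
#' reported.
#'
#' @param object A `cohort_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cohort_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$families,
    cols = c("expected_count", "observed_count"),
    names_to = "kind", values_to = "count"
  ) |>
    dplyr::mutate(kind = ifelse(.data$kind == "expected_count",
                                "expected", "observed"),
                  family_id = factor(.data$family_id,
                                     levels = unique(.data$family_id)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$family_id, y = .data$count,
                                     fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "family", y = "informative markers", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Detection-rate curves from a sensitivity assay
#'
#' @param data Output of [sensitivity_assay()], optionally row-bound
#'   over primers with a `primer_id` column.
#' @return A ggplot of detection rate against input mass (log scale).
#' @export
plot_sensitivity <- function(data) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$mass_ng,
                                          y = .data$detection_rate))
  if ("primer_id" %in% names(data)) {
    p <- p + ggplot2::aes(colour = .data$primer_id)
  }
  p + ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "input DNA (ng)", y = "detection rate") +
    ggplot2::theme_minimal()
}

#' Minor-allele peak heights across a mixture dilution series
#'
#' @param peaks Output of [mixture_series()].
#' @return A ggplot of peak height (RFU, log scale) against ratio, one
#'   line per locus, with the calling threshold marked.
#' @param threshold_rfu Detection threshold drawn as a reference line.
#' @export
plot_mixture_series <- function(peaks, threshold_rfu = 50) {
  ggplot2::ggplot(peaks, ggplot2::aes(x = .data$ratio,
                                      y = .data$height_rfu,
                                      colour = .data$primer_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$detected)) +
    ggplot2::geom_hline(yintercept = threshold_rfu, linetype = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "major:minor ratio", y = "peak height (RFU)",
                  colour = NULL, shape = "detected") +
    ggplot2::theme_minimal()
}

#' Fragment-length distribution of a fragmentation state
#'
#' @param state A [fragmentation_state()].
#' @param n Number of sampled fragments for the lognormal model /
#'   density grid for the exponential one.
#' @return A ggplot density of fragment lengths.
#' @export
plot_fragment_lengths <- function(state, n = 10000) {
  lengths <- switch(state$model,
    lognormal = sample_cffdna_length(n, state),
    exponential = stats::rexp(n, rate = 1 / state$mean_fragment_bp)
  )
  ggplot2::ggplot(tibble::tibble(length_bp = lengths),
                  ggplot2::aes(x = .data$length_bp)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "fragment length (bp)", y = "density") +
    ggplot2::theme_minimal()
}

#' Amplicon survival against fragment length
#'
#' @param comparison Output of [degraded_genotyping_comparison()].
#' @return A ggplot contrasting the short SNP-SNP amplicons with the
#'   long-amplicon comparison markers.
#' @export
plot_degradation_comparison <- function(comparison) {
  ggplot2::ggplot(comparison,
                  ggplot2::aes(x = .data$amplicon_bp,
                               y = .data$success_prob,
                               colour = .data$marker_class)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "amplicon length (bp)",
                  y = "genotyping success probability", colour = NULL) +
    ggplot2::theme_minimal()
}
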