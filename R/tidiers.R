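# broom-style accessors for pipeline result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cohort summary into per-family rows
#'
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @return The per-family tibble with a `detected_fraction` column.
#' @export
tidy.cohort_summary <- function(x, ...) {
  dplyr::mutate(
    x$families,
    detected_fraction = ifelse(.data$expected_count > 0,
                               .data$observed_count / .data$expected_count,
                               NA_real_)
  )
}

#' One-row overview of a cohort summary
#'
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @return A one-row tibble: `n_families`, `total_expected`,
#'   `total_observed`, `detection_rate_percent`.
#' @export
glance.cohort_summary <- function(x, ...) {
  tibble::tibble(
    n_families = nrow(x$families),
    total_expected = x$total_expected,
    total_observed = x$total_observed,
    detection_rate_percent = x$detection_rate_percent
  )
}

#' @rdname tidy.cohort_summary
#' @export
tidy.plasma_run <- function(x, ...) x$outcomes

#' @rdname glance.cohort_summary
#' @export
glance.plasma_run <- function(x, ...) glance(summarize_cohort(x))
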