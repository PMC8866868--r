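# Shared validation and numeric helpers.

#' Round half away from zero
#'
#' Commercial-rounding convention used for all reported means and rates
#' (base `round()` rounds half to even, which cannot reproduce e.g. a mean
#' of 45 from 45.47 alongside a rate of 98.7 from 98.7013 consistently
#' with hand-reported tables).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(45.47)   # 45
#' round_half_up(0.5)     # 1
#' round_half_up(98.7013, 1)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

dna_bases <- c("A", "C", "G", "T")

abort_format <- function(msg, ...) {
  rlang::abort(msg, class = "snpsnpmix_format_error", ...)
}

abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = "snpsnpmix_validation_error", ...)
}

abort_mendelian <- function(msg, ...) {
  rlang::abort(msg, class = "snpsnpmix_mendelian_error", ...)
}

check_columns <- function(data, cols, what = "input") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort_validation(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}
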