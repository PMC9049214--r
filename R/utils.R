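#' Round half away from zero
#'
#' Report tables print percentages rounded half away from zero (so 12.65
#' becomes 12.7), matching the convention of the statistical software the
#' original tables were produced with, not base R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(c(12.649, 12.65, -12.65))
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Format a percentage for reports
#'
#' @param x Numeric vector on the percent scale; `NA` renders as an em dash.
#' @param digits Decimal places.
#' @return Character vector.
#' @export
format_pct <- function(x, digits = 1) {
  out <- ifelse(
    is.na(x), "—",
    formatC(round_half_up(x, digits), format = "f", digits = digits)
  )
  as.character(out)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# internal: stop with a consistent prefix
abort_abx <- function(...) stop(..., call. = FALSE)
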