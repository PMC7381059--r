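#' Percentage with half-up rounding
#'
#' All reported percentages in the package go through this helper so that
#' printed values round half-up (5 rounds away from zero) rather than with
#' banker's rounding, matching how surveillance reports print ratios.
#'
#' @param n Numerator count.
#' @param d Denominator count. A zero denominator yields `NA` (not estimable).
#' @param digits Decimal places to keep (default 2).
#' @return Numeric percentage in `[0, 100]`, or `NA_real_` when `d == 0`.
#' @examples
#' pct(215, 8124)        # 2.65
#' pct(54, 56, digits = 0)  # 96
#' @export
pct <- function(n, d, digits = 2) {
  stopifnot(length(n) == length(d))
  out <- rep(NA_real_, length(n))
  ok <- !is.na(d) & d > 0 & !is.na(n)
  out[ok] <- round_half_up(100 * n[ok] / d[ok], digits)
  out
}

#' Round half-up
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return `x` rounded so that exact halves go away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Treat empty strings and whitespace-only strings as missing.
blank_to_na <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & !nzchar(trimws(x))] <- NA_character_
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
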