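#' Round half away from zero
#'
#' Plain decimal rounding where exact halves move away from zero, as used
#' when reporting percentages (e.g. 53/80 genes -> 66.3%). Base R's
#' `round()` rounds halves to even, which gives 66.2 for that case.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count, rounded to one decimal
#'
#' @param k Numerator count(s).
#' @param total Denominator count; must be positive.
#' @param digits Decimal digits (default 1, the reporting convention here).
#' @return `100 * k / total` rounded half away from zero.
#' @export
percent_of <- function(k, total, digits = 1) {
  if (length(total) != 1L || is.na(total) || total <= 0)
    stop("'total' must be a single positive count")
  round_half_away(100 * k / total, digits)
}

# internal: reverse complement of an ACGTN character scalar
revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# internal: derive a stream-specific 32-bit seed from a master seed
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 10007L * as.integer(offset)) %% 2147483587L
}

# internal: stop() with sprintf-style formatting
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
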