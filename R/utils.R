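# shared helpers: rounding, sequence ops, validation

#' Round half-up to a fixed number of decimals
#'
#' Base R `round()` rounds half to even; printed report percentages use
#' conventional half-up rounding (69.15 -> 69.2), so summaries go through
#' this helper.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# truncate toward zero at a fixed number of decimals (reporting style for
# expansion rates and specific/core ratios)
trunc_dec <- function(x, digits) {
  f <- 10^digits
  trunc(x * f) / f
}

# reverse complement of a plain character string (ACGTN)
revcomp <- function(s) {
  ints <- utf8ToInt(chartr("ACGTN", "TGCAN", s))
  intToUtf8(rev(ints))
}

# vectorised single-character complement on an already split vector
comp_chars <- function(v) chartr("ACGTN", "TGCAN", v)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(ok, fmt, ...) if (!isTRUE(ok)) stopf(fmt, ...)

# integer-exact fraction comparison: is a/b >= num/1e6 ?  Avoids float edges
# at thresholds like 0.03 by scaling both sides to integers.
frac_ge <- function(a, b, frac) {
  num <- round(frac * 1e6)
  a * 1e6 >= b * num
}

#' Variant key strings
#'
#' Normalized variant identity used for all cross-pool set algebra:
#' `contig:pos:ref:alt`. Frequencies and p-values are per-pool observations
#' and never part of identity.
#'
#' @param calls data frame with `contig`, `pos`, `ref`, `alt` columns
#' @return character vector of keys
#' @export
variant_key <- function(calls) {
  paste(calls$contig, calls$pos, calls$ref, calls$alt, sep = ":")
}
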