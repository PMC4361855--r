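# Sequence-level genome statistics: GC content, windowed GC skew,
# terminal-inverted-repeat detection on linear chromosomes.

#' GC content of a DNA sequence
#'
#' 100 * (G + C) / (A + C + G + T); N bases are excluded from both
#' numerator and denominator.
#'
#' @param seq DNA string or [genome_seq]
#' @param digits decimals to round to (half-up); `NA` for unrounded
#' @return percent GC
#' @export
gc_content <- function(seq, digits = 1) {
  if (inherits(seq, "genome_seq")) seq <- seq$sequence
  n <- nchar(seq)
  count <- function(ch) n - nchar(gsub(ch, "", seq, fixed = TRUE))
  g <- count("G"); c_ <- count("C"); a <- count("A"); t <- count("T")
  denom <- g + c_ + a + t
  if (denom == 0) stopf("gc_content undefined: no A/C/G/T bases")
  pct <- 100 * (g + c_) / denom
  if (is.na(digits)) pct else round_half_up(pct, digits)
}

#' Windowed GC skew
#'
#' (G - C) / (G + C) per window; windows with G + C = 0 emit 0 and are
#' flagged.
#'
#' @param seq DNA string or [genome_seq]
#' @param window_bp window size
#' @param step_bp step between window starts (default = window, i.e.
#'   non-overlapping)
#' @return data frame: `start`, `end`, `skew`, `undefined`
#' @export
gc_skew <- function(seq, window_bp, step_bp = window_bp) {
  if (inherits(seq, "genome_seq")) seq <- seq$sequence
  L <- nchar(seq)
  assert_that(window_bp <= L, "window (%d) exceeds sequence length (%d)",
              window_bp, L)
  starts <- seq.int(1L, L - window_bp + 1L, by = step_bp)
  wins <- substring(seq, starts, starts + window_bp - 1L)
  g <- nchar(wins) - nchar(gsub("G", "", wins, fixed = TRUE))
  c_ <- nchar(wins) - nchar(gsub("C", "", wins, fixed = TRUE))
  tot <- g + c_
  undef <- tot == 0
  skew <- ifelse(undef, 0, (g - c_) / ifelse(undef, 1, tot))
  data.frame(start = starts, end = starts + window_bp - 1L, skew = skew,
             undefined = undef)
}

#' Detect a terminal inverted repeat
#'
#' Compares the chromosome prefix position-by-position (ungapped) with the
#' reverse complement of its suffix and reports the largest length L whose
#' mismatch fraction stays within `max_mismatch_rate`; the scan stops after
#' 100 consecutive mismatches.
#'
#' @param seq DNA string or [genome_seq] (linear)
#' @param min_len minimum length to report (shorter maxima report 0)
#' @param max_mismatch_rate tolerated mismatch fraction over the repeat
#' @return list: `length`, `mismatch_count`, `gc_of_tir` (percent GC of
#'   the prefix copy; NA when length is 0)
#' @export
detect_tir <- function(seq, min_len = 100, max_mismatch_rate = 0.01) {
  if (inherits(seq, "genome_seq")) {
    assert_that(seq$topology == "linear", "TIR detection needs a linear genome")
    seq <- seq$sequence
  }
  L <- nchar(seq)
  half <- L %/% 2L
  pre <- strsplit(substr(seq, 1L, half), "", fixed = TRUE)[[1]]
  suf_rc <- comp_chars(rev(strsplit(substr(seq, L - half + 1L, L), "",
                                    fixed = TRUE)[[1]]))
  mism <- pre != suf_rc
  # stop the scan after 100 consecutive mismatches
  run <- 0L; cutoff <- half
  for (i in seq_len(half)) {
    if (mism[i]) {
      run <- run + 1L
      if (run >= 100L) { cutoff <- i; break }
    } else run <- 0L
  }
  cum <- cumsum(mism[seq_len(cutoff)])
  ok <- which(cum <= max_mismatch_rate * seq_len(cutoff))
  len <- if (length(ok) > 0) max(ok) else 0L
  if (len < min_len) len <- 0L
  list(length = len,
       mismatch_count = if (len > 0) cum[len] else 0L,
       gc_of_tir = if (len > 0) gc_content(substr(seq, 1, len)) else NA_real_)
}
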