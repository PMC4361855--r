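# Independent reference oracles, deliberately written as brute-force or
# closed-form implementations separate from the package's code paths.

# exact binomial upper tail P(X >= k), X ~ Binomial(n, p), by direct sum
binom_tail_oracle <- function(k, n, p) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  sum(exp(lchoose(n, k:n) + (k:n) * log(p) + (n - (k:n)) * log1p(-p)))
}

# exact hypergeometric upper tail P(X >= k) for k successes drawn in n
# from N with K marked, by direct sum of the pmf
hyper_tail_oracle <- function(k, K, N, n) {
  hi <- min(K, n)
  if (k <= max(0, n - (N - K))) return(1)
  if (k > hi) return(0)
  i <- k:hi
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Benjamini-Hochberg step-up, written directly from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# union-find connected components over an edge list
union_find_oracle <- function(ids, from, to) {
  parent <- setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_along(from)) {
    ra <- find(from[i]); rb <- find(to[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(ids, find, "")
  # label each component by its lexicographically smallest member
  comp <- split(ids, roots)
  lab <- vapply(comp, min, "")
  setNames(lab[roots], ids)
}

# full Smith-Waterman DP with affine gaps (cost of a gap of length L =
# open + L * ext) over BLOSUM62, with traceback for identity
sw_oracle <- function(a, b, open = 11, ext = 1) {
  B <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  best <- 0; bi <- 0; bj <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- B[av[i - 1], bv[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1], Ix[i - 1, j - 1],
                     Iy[i - 1, j - 1]) + s
      if (M[i, j] < 0) M[i, j] <- max(0, M[i, j])
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
      if (M[i, j] > best) { best <- M[i, j]; bi <- i; bj <- j }
    }
  }
  # traceback from the best M cell for matched columns / total columns
  matches <- 0; cols <- 0
  i <- bi; j <- bj; state <- "M"
  while (i > 1 && j > 1) {
    if (state == "M") {
      if (M[i, j] <= 0 && cols > 0) break
      s <- B[av[i - 1], bv[j - 1]]
      cols <- cols + 1
      if (av[i - 1] == bv[j - 1]) matches <- matches + 1
      prev <- M[i, j] - s
      if (abs(prev) < 1e-9 && M[i - 1, j - 1] < 1e-9 &&
          Ix[i - 1, j - 1] < 1e-9 && Iy[i - 1, j - 1] < 1e-9) {
        i <- i - 1; j <- j - 1
        break
      }
      if (abs(prev - M[i - 1, j - 1]) < 1e-9) state <- "M"
      else if (abs(prev - Ix[i - 1, j - 1]) < 1e-9) state <- "Ix"
      else state <- "Iy"
      i <- i - 1; j <- j - 1
    } else if (state == "Ix") {
      cols <- cols + 1
      if (abs(Ix[i, j] - (M[i - 1, j] - open - ext)) < 1e-9) state <- "M"
      i <- i - 1
    } else {
      cols <- cols + 1
      if (abs(Iy[i, j] - (M[i, j - 1] - open - ext)) < 1e-9) state <- "M"
      j <- j - 1
    }
  }
  list(score = best,
       identity = if (cols > 0) 100 * matches / cols else 0)
}

# analytic recall prediction for a planted SNV at pooled frequency f:
# depth ~ Poisson(mean_depth), alt reads ~ Binomial(depth, f(1-e)+(1-f)e/3),
# passed through the caller's gates (coverage, frequency, binomial-tail
# significance at the phred-discretized error rate, strand balance)
caller_sensitivity_prediction <- function(f, mean_depth, e,
                                          min_coverage = 50,
                                          min_var_freq = 0.03,
                                          p_threshold = 0.01,
                                          min_strand_frac = 0.1) {
  q <- if (e > 0) round(-10 * log10(e)) else 40
  eq <- 10^(-q / 10)
  p_alt <- f * (1 - e) + (1 - f) * e / 3
  dmin <- max(min_coverage, qpois(1e-12, mean_depth))
  dmax <- qpois(1e-12, mean_depth, lower.tail = FALSE)
  strand_ok <- function(a) {
    lo <- ceiling(min_strand_frac * a - 1e-9)
    hi <- floor(a * (1 - min_strand_frac) + 1e-9)
    if (lo > hi) 0 else pbinom(hi, a, 0.5) - pbinom(lo - 1, a, 0.5)
  }
  total <- 0
  for (d in dmin:dmax) {
    a_vals <- 0:d
    tails <- pbinom(a_vals - 1, d, eq, lower.tail = FALSE)
    a_p <- a_vals[which(tails <= p_threshold)[1]]
    a_min <- max(ceiling(min_var_freq * d - 1e-9), a_p, 1)
    if (a_min > d) next
    aa <- a_min:d
    total <- total + dpois(d, mean_depth) *
      sum(dbinom(aa, d, p_alt) * vapply(aa, strand_ok, 0))
  }
  total
}

# whole-protein retranslation oracle for coding SNVs: mutate the genome,
# re-extract the CDS, translate both, diff
retranslate_oracle <- function(genome, gene, pos, alt) {
  seq0 <- genome$sequence
  seq1 <- seq0
  substr(seq1, pos, pos) <- alt
  get_prot <- function(s) {
    cds <- substr(s, gene$start, gene$end)
    if (gene$strand == "-")
      cds <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds)))
    as.character(Biostrings::translate(
      Biostrings::DNAString(cds),
      genetic.code = Biostrings::getGeneticCode("11"),
      if.fuzzy.codon = "X", no.init.codon = TRUE))
  }
  p0 <- get_prot(seq0); p1 <- get_prot(seq1)
  if (p0 == p1) return(list(class = "synonymous SNV", aa_change = NA))
  d <- which(strsplit(p0, "")[[1]] != strsplit(p1, "")[[1]])
  a0 <- substr(p0, d, d); a1 <- substr(p1, d, d)
  cls <- if (a0 != "*" && a1 == "*") "stopgain SNV"
  else if (a0 == "*" && a1 != "*") "stoploss SNV"
  else "nonsynonymous SNV"
  list(class = cls, aa_change = paste0(a0, d, a1))
}
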