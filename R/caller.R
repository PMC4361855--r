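# Pooled variant calling from a filtered pileup, VarScan2-style.
#
# Decision per non-reference allele at a site:
#   depth >= min_coverage
#   AND alt_count / depth >= min_var_freq          (>=, compared in exact
#                                                   integer arithmetic)
#   AND P(X >= alt_count | X ~ Binomial(depth, e)) <= p_threshold,
#       with e = 10^(-mean_baseq / 10) from the site's retained bases
#   AND, when the strand filter is on, at least min_strand_fraction of the
#       alt reads on each strand.
# The binomial one-sided tail is the simplest defensible null for "more
# alt reads than sequencing error explains"; it is exposed in the config
# rather than hidden.

#' Caller configuration
#'
#' Defaults are the thresholds of the pooled analysis this package
#' re-implements: minimum coverage 50, minimum variant frequency 0.03,
#' strand filter on (VarScan2's documented behavior class: >= 10% of
#' variant reads on each strand), base quality floor 20, mapping quality
#' floor 10, significance 0.01 (the VarScan2 documented default).
#'
#' @param min_coverage minimum filtered depth to consider a site
#' @param min_var_freq minimum alt-read fraction (inclusive)
#' @param strand_filter require alt support on both strands
#' @param min_baseq base-quality floor applied at pileup ingestion
#' @param min_mapq mapping-quality floor applied at pileup ingestion
#' @param p_threshold maximum binomial error-model p-value
#' @param min_strand_fraction per-strand minimum fraction of alt reads
#'   when `strand_filter` is on
#' @return a `caller_config` list
#' @export
caller_config <- function(min_coverage = 50, min_var_freq = 0.03,
                          strand_filter = TRUE, min_baseq = 20,
                          min_mapq = 10, p_threshold = 0.01,
                          min_strand_fraction = 0.10) {
  assert_that(min_var_freq > 0 && min_var_freq < 1,
              "min_var_freq must be in (0, 1)")
  assert_that(min_strand_fraction >= 0 && min_strand_fraction <= 0.5,
              "min_strand_fraction must be in [0, 0.5]")
  structure(list(min_coverage = min_coverage, min_var_freq = min_var_freq,
                 strand_filter = strand_filter, min_baseq = min_baseq,
                 min_mapq = min_mapq, p_threshold = p_threshold,
                 min_strand_fraction = min_strand_fraction),
            class = "caller_config")
}

# vectorized decision core shared by call_site and call_pool
call_core <- function(sites, alleles, config, pool_id) {
  if (nrow(alleles) == 0) return(empty_calls())
  s <- sites[alleles$site, , drop = FALSE]
  is_indel <- grepl("^[+-]", alleles$allele)
  nonref <- is_indel | alleles$allele != s$ref_base
  cand <- which(nonref)
  if (length(cand) == 0) return(empty_calls())
  a <- alleles[cand, , drop = FALSE]
  s <- s[cand, , drop = FALSE]
  is_indel <- is_indel[cand]
  alt_count <- a$fwd + a$rev
  depth <- s$depth
  keep <- depth >= config$min_coverage &
    alt_count > 0 &
    frac_ge(alt_count, depth, config$min_var_freq)
  e <- 10^(-s$mean_baseq / 10)
  pval <- pbinom(alt_count - 1L, depth, e, lower.tail = FALSE)
  keep <- keep & pval <= config$p_threshold
  if (isTRUE(config$strand_filter)) {
    keep <- keep &
      frac_ge(a$fwd, alt_count, config$min_strand_fraction) &
      frac_ge(a$rev, alt_count, config$min_strand_fraction)
  }
  if (!any(keep)) return(empty_calls())
  a <- a[keep, , drop = FALSE]
  s <- s[keep, , drop = FALSE]
  is_indel <- is_indel[keep]
  alt_count <- alt_count[keep]
  pval <- pval[keep]
  ref <- s$ref_base
  alt <- a$allele
  vtype <- rep("SNV", nrow(a))
  ins <- startsWith(alt, "+")
  del <- startsWith(alt, "-")
  seqs <- substr(alt, 2, nchar(alt))
  alt[ins] <- paste0(ref[ins], seqs[ins])
  ref[del] <- paste0(s$ref_base[del], seqs[del])
  alt[del] <- s$ref_base[del]
  vtype[ins] <- "insertion"
  vtype[del] <- "deletion"
  data.frame(contig = s$contig, pos = s$pos, ref = ref, alt = alt,
             vtype = vtype, depth = s$depth, alt_count = alt_count,
             var_freq = alt_count / s$depth, alt_fwd = a$fwd,
             alt_rev = a$rev, p_value = pval, pool_id = pool_id,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call variants at a single pileup site
#'
#' @param site one-row `sites` entry of a `pileup` object (or a list with
#'   fields `contig`, `pos`, `ref_base`, `depth`, `mean_baseq`)
#' @param alleles allele rows for that site (`allele`, `fwd`, `rev`)
#' @param config a [caller_config]
#' @param pool_id pool label recorded on emitted calls
#' @return variant-call data frame (zero or more rows; zero depth is not
#'   an error, it simply yields no call)
#' @export
call_site <- function(site, alleles, config = caller_config(),
                      pool_id = "pool") {
  sites <- data.frame(contig = site$contig, pos = site$pos,
                      ref_base = site$ref_base, depth = site$depth,
                      mean_baseq = site$mean_baseq, stringsAsFactors = FALSE)
  al <- alleles
  al$site <- rep(1L, nrow(al))
  call_core(sites, al, config, pool_id)
}

#' Call variants over a whole pileup
#'
#' Sites must be sorted by (contig, pos); the output preserves site order
#' and, within a site, allele order.
#'
#' @param pu a `pileup` object from [read_pileup]
#' @param config a [caller_config]
#' @param pool_id pool label recorded on emitted calls
#' @return sorted variant-call data frame
#' @export
call_pool <- function(pu, config = caller_config(), pool_id = "pool") {
  s <- pu$sites
  if (nrow(s) > 1) {
    o <- order(s$contig, s$pos)
    inv <- which(o != seq_len(nrow(s)))
    if (length(inv) > 0)
      stopf("pileup not sorted by (contig, pos): first inversion at row %d",
            inv[1])
  }
  call_core(pu$sites, pu$alleles, config, pool_id)
}
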