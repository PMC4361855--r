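# Pool set algebra and category summaries.
#
# Variant identity for cross-pool comparison is the normalized 4-tuple
# (contig, pos, ref, alt); per-pool frequencies and p-values never enter
# identity.  The shared/specific partition and its percentages are the
# pipeline's headline numbers.

#' Compare the variant sets of two pools
#'
#' Exact set algebra on normalized variant keys.  Shared fractions are
#' reported as percentages of each pool, rounded half-up to one decimal.
#'
#' @param calls_low variant calls (or any data frame with
#'   `contig`/`pos`/`ref`/`alt`) for the low pool
#' @param calls_high same for the high pool
#' @return list with `shared`, `specific_low`, `specific_high` (key
#'   vectors), the corresponding counts `n_low`, `n_high`, `n_shared`,
#'   `n_specific_low`, `n_specific_high`, and `pct_shared_low`,
#'   `pct_shared_high`
#' @export
compare_pools <- function(calls_low, calls_high) {
  kl <- variant_key(calls_low)
  kh <- variant_key(calls_high)
  if (anyDuplicated(kl))
    stopf("duplicate variant key in low pool: %s", kl[duplicated(kl)][1])
  if (anyDuplicated(kh))
    stopf("duplicate variant key in high pool: %s", kh[duplicated(kh)][1])
  shared <- intersect(kl, kh)
  sl <- setdiff(kl, kh)
  sh <- setdiff(kh, kl)
  list(shared = shared, specific_low = sl, specific_high = sh,
       n_low = length(kl), n_high = length(kh), n_shared = length(shared),
       n_specific_low = length(sl), n_specific_high = length(sh),
       pct_shared_low = round_half_up(100 * length(shared) /
                                        max(length(kl), 1), 1),
       pct_shared_high = round_half_up(100 * length(shared) /
                                         max(length(kh), 1), 1))
}

#' Summarize annotated group-specific variants by category
#'
#' Produces the per-category count table plus roll-ups: non-coding total,
#' coding total, amino-acid-changing total (nonsynonymous + frameshift +
#' nonframeshift + stopgain + stoploss), near-gene total (upstream +
#' downstream + upstream;downstream) and the grand total, with
#' amino-acid-changing percentages rounded half-up to one decimal.
#'
#' @param annotated_low annotated variants specific to the low pool
#' @param annotated_high annotated variants specific to the high pool
#' @return list with `table` (data frame: `region_class`, `low`, `high`)
#'   and `rollup` (data frame of the derived totals per pool)
#' @export
summarize_categories <- function(annotated_low, annotated_high) {
  count_one <- function(ann) {
    if (nrow(ann) > 0) {
      unknown <- setdiff(unique(ann$region_class), REGION_CLASSES)
      if (length(unknown) > 0)
        stopf("unknown category label: %s", unknown[1])
    }
    vapply(REGION_CLASSES, function(cl) sum(ann$region_class == cl), 0L)
  }
  low <- count_one(annotated_low)
  high <- count_one(annotated_high)
  tab <- data.frame(region_class = REGION_CLASSES, low = unname(low),
                    high = unname(high), stringsAsFactors = FALSE)
  noncoding_classes <- c("intergenic", NEAR_GENE_CLASSES)
  coding_classes <- setdiff(REGION_CLASSES, noncoding_classes)
  roll <- function(counts) {
    total <- sum(counts)
    aa <- sum(counts[AA_CHANGING_CLASSES])
    c(non_coding = sum(counts[noncoding_classes]),
      coding = sum(counts[coding_classes]),
      aa_changing = aa,
      near_gene = sum(counts[NEAR_GENE_CLASSES]),
      total = total,
      pct_aa_changing = round_half_up(100 * aa / max(total, 1), 1))
  }
  rl <- roll(low); rh <- roll(high)
  rollup <- data.frame(quantity = names(rl), low = unname(rl),
                       high = unname(rh), stringsAsFactors = FALSE)
  list(table = tab, rollup = rollup)
}

#' Genes with amino-acid-changing variants in either group
#'
#' Union over both group-specific annotated sets of the gene ids whose
#' variant class changes the protein, deduplicated.
#'
#' @param annotated_low annotated low-specific variants
#' @param annotated_high annotated high-specific variants
#' @return character vector of gene ids
#' @export
affected_genes <- function(annotated_low, annotated_high) {
  pick <- function(ann) {
    if (nrow(ann) == 0) return(character(0))
    hit <- ann$region_class %in% AA_CHANGING_CLASSES
    unlist(strsplit(ann$gene_ids[hit], ";", fixed = TRUE))
  }
  ids <- union(pick(annotated_low), pick(annotated_high))
  sort(ids[nzchar(ids)])
}
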