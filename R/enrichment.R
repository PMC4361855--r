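# Fisher-exact (one-sided hypergeometric) category over-representation
# with Benjamini-Hochberg FDR across tested categories.

#' Category enrichment of a study gene set
#'
#' For each category, tests whether the study set contains more genes of
#' that category than expected from the background: one-sided
#' hypergeometric upper tail, p = P(X >= k) with K category genes among N
#' background genes and a study set of size n.  Genes may carry several
#' labels (they count once per label; N counts genes).  P-values are
#' BH-adjusted across all tested categories.
#'
#' @param study character vector of study gene ids (subset of background)
#' @param background data frame with `gene_id` and `category` (a gene id
#'   may appear on several rows, one per label)
#' @param cutoff significance cutoff (default 0.01)
#' @param cutoff_on apply the cutoff to `"fdr"` (default) or `"p"`
#' @return data frame sorted by p: `category`, `k`, `n`, `K`, `N`,
#'   `p_value`, `fdr`, `significant`
#' @export
fisher_enrichment <- function(study, background, cutoff = 0.01,
                              cutoff_on = c("fdr", "p")) {
  cutoff_on <- match.arg(cutoff_on)
  genes <- unique(background$gene_id)
  missing <- setdiff(study, genes)
  if (length(missing) > 0)
    stopf("study gene absent from background: %s", missing[1])
  cats <- sort(unique(background$category))
  assert_that(length(cats) >= 1, "background has no categories")
  N <- length(genes)
  n <- length(unique(study))
  res <- lapply(cats, function(cl) {
    members <- unique(background$gene_id[background$category == cl])
    K <- length(members)
    k <- length(intersect(study, members))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(category = cl, k = k, n = n, K = K, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out$significant <- if (cutoff_on == "fdr") out$fdr <= cutoff
                     else out$p_value <= cutoff
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}
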