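# Pan-genome analysis: protein-family clustering across species and
# core/dispensable/specific statistics.
#
# Family definitions follow the classic pan-genome partition over a panel
# of species: core = family present in every species of the panel,
# specific = present in exactly one, dispensable = everything in between.
# Clustering is single-linkage connected components over similarity edges
# passing identity > 50%, coverage > 70% (min of query/subject by default)
# and the significance gate (E <= 1e-5 for ingested BLAST hits; a raw
# alignment-score floor for built-in alignments, which have no E-value).

#' Pairwise protein similarity
#'
#' Local (Smith-Waterman) alignment with BLOSUM62 and affine gaps
#' (open 11, extend 1).  Identity is exact matches over aligned columns
#' (columns where either residue is X are excluded from the numerator);
#' coverage is the aligned span over each sequence's length.
#'
#' @param a,b amino-acid sequence strings
#' @param gap_opening,gap_extension affine gap penalties
#' @return one-row similarity-edge data frame (`query_id` = "a",
#'   `subject_id` = "b" unless names are supplied via `ida`/`idb`)
#' @param ida,idb sequence ids recorded on the edge
#' @export
pairwise_similarity <- function(a, b, ida = "a", idb = "b",
                                gap_opening = 11, gap_extension = 1) {
  assert_that(nzchar(a) && nzchar(b), "empty sequence in pairwise_similarity")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension)
  pa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  cols <- length(pa)
  usable <- pa != "X" & pb != "X"
  matches <- sum(pa == pb & pa != "-" & usable)
  ident <- if (cols > 0) 100 * matches / cols else 0
  span_a <- Biostrings::width(Biostrings::pattern(aln)@range)
  span_b <- Biostrings::width(Biostrings::subject(aln)@range)
  data.frame(query_id = ida, subject_id = idb,
             pct_identity = ident,
             cov_query = span_a / nchar(a),
             cov_subject = span_b / nchar(b),
             evalue = NA_real_, score = Biostrings::score(aln),
             stringsAsFactors = FALSE)
}

#' All-vs-all similarity edges for a protein table
#'
#' Runs [pairwise_similarity] over every unordered pair; intended for
#' desk-scale protein sets.  Pairs whose length ratio (shorter/longer)
#' falls below `min_length_ratio` are skipped: an ungapped-span coverage
#' of the longer sequence can essentially never clear a coverage
#' threshold at that ratio, so this mirrors the prescreen any all-vs-all
#' search applies in practice.  Set it to 0 to align every pair.
#'
#' @param proteins data frame with `protein_id`, `sequence`
#' @param min_length_ratio length-ratio prescreen (default 0.70, matching
#'   the default clustering coverage)
#' @return similarity-edge data frame
#' @export
all_vs_all_similarity <- function(proteins, min_length_ratio = 0.70) {
  n <- nrow(proteins)
  lens <- nchar(proteins$sequence)
  out <- vector("list", n * (n - 1) %/% 2)
  k <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (min(lens[i], lens[j]) < min_length_ratio * max(lens[i], lens[j]))
        next
      k <- k + 1L
      out[[k]] <- pairwise_similarity(
        proteins$sequence[i], proteins$sequence[j],
        proteins$protein_id[i], proteins$protein_id[j])
    }
  }
  if (k == 0) {
    return(data.frame(query_id = character(), subject_id = character(),
                      pct_identity = numeric(), cov_query = numeric(),
                      cov_subject = numeric(), evalue = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out[seq_len(k)])
}

#' Cluster proteins into families
#'
#' Edges passing identity > `min_identity`, min(query, subject) coverage
#' > `min_coverage` (mode configurable) and the significance gate are kept;
#' families are the connected components (single linkage).  Proteins with
#' no qualifying edge are singleton families.  Family ids are stable: the
#' lexicographically smallest member id.
#'
#' @param proteins data frame with `protein_id`, `species_id` (and
#'   optionally `sequence`, `chrom_pos`, `chrom_length`)
#' @param edges similarity-edge data frame ([read_blast_tab] or
#'   [pairwise_similarity] output)
#' @param min_identity percent identity threshold (exclusive)
#' @param min_coverage coverage threshold (exclusive)
#' @param coverage_mode which coverage must pass: `"min"` (both), or
#'   `"query"` / `"subject"` only
#' @param max_evalue significance gate for edges that carry an E-value
#' @param min_score raw-score floor for built-in alignment edges (which
#'   have no E-value)
#' @return data frame: `protein_id`, `species_id`, `family_id`
#' @export
cluster_families <- function(proteins, edges, min_identity = 50,
                             min_coverage = 0.70,
                             coverage_mode = c("min", "query", "subject"),
                             max_evalue = 1e-5, min_score = 50) {
  coverage_mode <- match.arg(coverage_mode)
  ids <- proteins$protein_id
  if (nrow(edges) > 0) {
    unknown <- setdiff(unique(c(edges$query_id, edges$subject_id)), ids)
    if (length(unknown) > 0)
      stopf("edge references unknown protein: %s", unknown[1])
    cov_ok <- switch(coverage_mode,
      min = pmin(edges$cov_query, edges$cov_subject) > min_coverage,
      query = edges$cov_query > min_coverage,
      subject = edges$cov_subject > min_coverage)
    sig_ok <- ifelse(is.na(edges$evalue), edges$score >= min_score,
                     edges$evalue <= max_evalue)
    keep <- edges$pct_identity > min_identity & cov_ok & sig_ok &
      edges$query_id != edges$subject_id
    edges <- edges[keep, , drop = FALSE]
  }
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(edges) > 0)
    g <- igraph::add_edges(g, rbind(match(edges$query_id, ids),
                                    match(edges$subject_id, ids)))
  comp <- igraph::components(g)$membership
  fam <- vapply(split(ids, comp), function(m) min(m), character(1))
  data.frame(protein_id = ids, species_id = proteins$species_id,
             family_id = unname(fam[as.character(comp)]),
             stringsAsFactors = FALSE)
}

#' Classify families and summarize the pan-genome
#'
#' Family class by species presence: core = all species of the panel,
#' specific = exactly one, dispensable otherwise.  Per species:
#' gene counts per class, expansion rate of the core (that species' core
#' gene count / number of core families, truncated to 2 decimals) and the
#' specific/core gene-count ratio (truncated to 3 decimals).  When `species_meta`
#' carries a `genome_size` column, per-class counts are correlated with
#' genome size (squared Pearson r and two-sided p).
#'
#' @param membership data frame from [cluster_families]
#' @param species_meta data frame with `species_id` and optional
#'   `genome_size`
#' @return list with `families` (family_id, n_members, n_species, class),
#'   `per_species` (gene counts, expansion rate, specific/core ratio),
#'   `family_class_counts`, and `correlations` (when genome sizes given)
#' @export
classify_and_summarize <- function(membership, species_meta) {
  species <- unique(species_meta$species_id)
  assert_that(length(species) >= 2,
              "pan-genome classes need at least two species")
  n_species_total <- length(species)
  sp_by_fam <- split(membership$species_id, membership$family_id)
  fam_nsp <- vapply(sp_by_fam, function(s) length(unique(s)), 0L)
  fam_class <- ifelse(fam_nsp == n_species_total, "core",
                      ifelse(fam_nsp == 1L, "specific", "dispensable"))
  families <- data.frame(family_id = names(sp_by_fam),
                         n_members = lengths(sp_by_fam),
                         n_species = fam_nsp,
                         class = unname(fam_class),
                         stringsAsFactors = FALSE, row.names = NULL)
  n_core_fam <- sum(families$class == "core")
  memb_class <- families$class[match(membership$family_id,
                                     families$family_id)]
  per_species <- do.call(rbind, lapply(species, function(sp) {
    sel <- membership$species_id == sp
    tot <- sum(sel)
    core <- sum(sel & memb_class == "core")
    disp <- sum(sel & memb_class == "dispensable")
    spec <- sum(sel & memb_class == "specific")
    data.frame(species_id = sp, total_genes = tot, core_genes = core,
               dispensable_genes = disp, specific_genes = spec,
               expansion_rate = if (n_core_fam > 0)
                 trunc_dec(core / n_core_fam, 2) else NA_real_,
               specific_core_ratio = if (core > 0)
                 trunc_dec(spec / core, 3) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  stopifnot(all(per_species$core_genes + per_species$dispensable_genes +
                  per_species$specific_genes == per_species$total_genes))
  class_counts <- table(factor(families$class,
                               levels = c("core", "dispensable", "specific")))
  correlations <- NULL
  if ("genome_size" %in% names(species_meta)) {
    gs <- species_meta$genome_size[match(per_species$species_id,
                                         species_meta$species_id)]
    correlations <- do.call(rbind, lapply(
      c("core_genes", "dispensable_genes", "specific_genes", "total_genes"),
      function(col) {
        ct <- suppressWarnings(cor.test(per_species[[col]], gs))
        data.frame(count = col, r_squared = unname(ct$estimate)^2,
                   p_value = ct$p.value, stringsAsFactors = FALSE)
      }))
  }
  list(families = families, per_species = per_species,
       family_class_counts = as.integer(class_counts),
       family_class_labels = names(class_counts),
       correlations = correlations)
}

#' Gene density along chromosomes per family class
#'
#' Fixed-bp bins (default 400 kb) along each species' chromosome; per bin
#' the proportion of that species' genes of each class, with bin midpoints
#' also expressed as percent of chromosome length.  Proportions per
#' (species, class) sum to 1.
#'
#' @param proteins data frame with `protein_id`, `species_id`,
#'   `chrom_pos`, `chrom_length`
#' @param membership family membership from [cluster_families]
#' @param species_meta species table (panel definition for classes)
#' @param bin_bp bin size in bp
#' @return data frame: `species_id`, `class`, `bin`, `bin_start`,
#'   `pct_chrom`, `proportion`
#' @export
density_profile <- function(proteins, membership, species_meta,
                            bin_bp = 400000) {
  missing <- proteins$protein_id[is.na(proteins$chrom_pos) |
                                   is.na(proteins$chrom_length)]
  if (length(missing) > 0)
    stopf("missing chromosome position for: %s",
          paste(head(missing, 3), collapse = ", "))
  cls <- classify_and_summarize(membership, species_meta)
  memb_class <- cls$families$class[match(membership$family_id,
                                         cls$families$family_id)]
  prot_class <- memb_class[match(proteins$protein_id,
                                 membership$protein_id)]
  out <- list()
  for (sp in unique(proteins$species_id)) {
    sel <- proteins$species_id == sp
    clen <- proteins$chrom_length[sel][1]
    n_bins <- max(1L, as.integer(ceiling(clen / bin_bp)))
    for (cl in c("core", "dispensable", "specific")) {
      psel <- sel & prot_class == cl
      n_cl <- sum(psel)
      if (n_cl == 0) next
      bins <- pmin(((proteins$chrom_pos[psel] - 1) %/% bin_bp) + 1L, n_bins)
      counts <- tabulate(bins, nbins = n_bins)
      out[[length(out) + 1L]] <- data.frame(
        species_id = sp, class = cl, bin = seq_len(n_bins),
        bin_start = (seq_len(n_bins) - 1L) * bin_bp + 1,
        pct_chrom = 100 * ((seq_len(n_bins) - 0.5) * bin_bp) / clen,
        proportion = counts / n_cl, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
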