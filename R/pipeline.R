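# End-to-end driver: simulate -> call (both pools) -> annotate -> compare
# -> summarize -> enrich, with a machine-readable run manifest.  Each
# stage is an exported function of its own; this wrapper only threads the
# objects through and writes the report bundle.

#' Pipeline configuration
#'
#' Merges the simulation and caller configurations with the annotator
#' window, enrichment cutoff and pan-genome thresholds, plus the global
#' seed and output directory.
#'
#' @param sim a [simulation_config]
#' @param caller a [caller_config]
#' @param window_bp near-gene annotation window
#' @param enrichment_cutoff significance cutoff for category enrichment
#' @param min_identity,min_coverage,max_evalue,bin_bp pan-genome thresholds
#'   (recorded in the manifest; the pan-genome stage runs separately)
#' @param out_dir output directory (created if needed); NULL = no files
#' @param seed global seed; overrides `sim$seed` when given
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(sim = simulation_config(),
                            caller = caller_config(),
                            window_bp = 300, enrichment_cutoff = 0.01,
                            min_identity = 50, min_coverage = 0.70,
                            max_evalue = 1e-5, bin_bp = 400000,
                            out_dir = NULL, seed = NULL) {
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, caller = caller, window_bp = window_bp,
                 enrichment_cutoff = enrichment_cutoff,
                 min_identity = min_identity, min_coverage = min_coverage,
                 max_evalue = max_evalue, bin_bp = bin_bp,
                 out_dir = out_dir, seed = sim$seed),
            class = "pipeline_config")
}

#' Run the pooled variant-discovery pipeline end to end
#'
#' Simulates a genome and two mutagenized pools, sequences them into
#' pileups, calls variants per pool, annotates, performs the pool set
#' algebra and Table-style category summary, and tests category
#' enrichment of the affected genes.  When `config$out_dir` is set, the
#' full report bundle (FASTA, GFF3, pileups, truth TSVs, VCFs, annotated
#' TSVs, summary TSV, enrichment TSV, manifest JSON) is written there.
#' Deterministic for a fixed config.
#'
#' @param config a [pipeline_config]
#' @return list with all stage outputs: `genome`, `models`, `truth_low`,
#'   `truth_high`, `calls_low`, `calls_high`, `comparison`,
#'   `annotated_low`, `annotated_high`, `summary`, `enrichment`,
#'   `recovery_low`, `recovery_high`, `manifest`
#' @export
run_end_to_end <- function(config = pipeline_config()) {
  sim <- config$sim
  gen <- generate_genome(sim)
  pools <- list()
  for (pid in c("L", "H")) {
    mut <- mutagenize_pool(gen$genome, gen$models, sim, pid)
    pu_sim <- simulate_pileup(gen$genome, mut$truth, sim,
                              seed = sim$seed + 17L +
                                match(pid, c("L", "H")))
    pu <- decode_pileup_lines(pu_sim$lines, config$caller$min_baseq,
                              config$caller$min_mapq)
    calls <- call_pool(pu, config$caller, pool_id = pid)
    pools[[pid]] <- list(truth = mut$truth, lines = pu_sim$lines,
                         calls = calls)
  }
  comparison <- compare_pools(pools$L$calls, pools$H$calls)
  key_l <- variant_key(pools$L$calls)
  key_h <- variant_key(pools$H$calls)
  ann_l <- annotate_set(pools$L$calls[key_l %in% comparison$specific_low, ,
                                      drop = FALSE],
                        gen$genome, gen$models, config$window_bp)
  ann_h <- annotate_set(pools$H$calls[key_h %in% comparison$specific_high, ,
                                      drop = FALSE],
                        gen$genome, gen$models, config$window_bp)
  summary <- summarize_categories(ann_l, ann_h)
  study <- affected_genes(ann_l, ann_h)
  background <- data.frame(gene_id = gen$models$gene_id,
                           category = gen$models$category_label,
                           stringsAsFactors = FALSE)
  enrich <- if (length(study) > 0)
    fisher_enrichment(study, background, config$enrichment_cutoff) else NULL
  manifest <- list(
    package = "poolvar",
    version = as.character(utils::packageVersion("poolvar")),
    seed = sim$seed,
    thresholds = list(
      min_coverage = config$caller$min_coverage,
      min_var_freq = config$caller$min_var_freq,
      strand_filter = config$caller$strand_filter,
      min_baseq = config$caller$min_baseq,
      min_mapq = config$caller$min_mapq,
      p_threshold = config$caller$p_threshold,
      window_bp = config$window_bp,
      enrichment_cutoff = config$enrichment_cutoff,
      pangenome_min_identity = config$min_identity,
      pangenome_min_coverage = config$min_coverage,
      pangenome_max_evalue = config$max_evalue,
      density_bin_bp = config$bin_bp),
    simulation = unclass(sim))
  out <- list(genome = gen$genome, models = gen$models,
              truth_low = pools$L$truth, truth_high = pools$H$truth,
              calls_low = pools$L$calls, calls_high = pools$H$calls,
              comparison = comparison, annotated_low = ann_l,
              annotated_high = ann_h, summary = summary,
              enrichment = enrich,
              recovery_low = evaluate_recovery(pools$L$calls, pools$L$truth),
              recovery_high = evaluate_recovery(pools$H$calls,
                                                pools$H$truth),
              manifest = manifest)
  if (!is.null(config$out_dir)) write_bundle(out, pools, config)
  out
}

write_bundle <- function(out, pools, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  write_fasta(out$genome, p("genome.fa"))
  write_gff3(out$models, p("models.gff3"))
  lens <- setNames(nchar(out$genome$sequence), out$genome$contig_id)
  for (pid in c("L", "H")) {
    writeLines(pools[[pid]]$lines, p(sprintf("pool_%s.pileup", pid)))
    write_truth_tsv(pools[[pid]]$truth, p(sprintf("truth_%s.tsv", pid)))
    write_vcf(pools[[pid]]$calls, p(sprintf("calls_%s.vcf", pid)), lens)
  }
  utils::write.table(out$annotated_low, p("annotated_L_specific.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(out$annotated_high, p("annotated_H_specific.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(out$summary$table, p("category_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(out$summary$rollup, p("category_rollup.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(out$enrichment))
    utils::write.table(out$enrichment, p("enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(out$manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(NULL)
}

#' Compare calls against a planted truth set
#'
#' @param calls variant-call data frame
#' @param truth truth set from [mutagenize_pool]
#' @return list with overall `sensitivity`, `precision`, counts, and
#'   `by_k` (per carrier count: truth sites, recovered, sensitivity)
#' @export
evaluate_recovery <- function(calls, truth) {
  ck <- variant_key(calls)
  tk <- variant_key(truth)
  tp <- sum(tk %in% ck)
  by_k <- do.call(rbind, lapply(sort(unique(truth$k)), function(kk) {
    sel <- truth$k == kk
    data.frame(k = kk, n_truth = sum(sel),
               n_recovered = sum(tk[sel] %in% ck),
               sensitivity = sum(tk[sel] %in% ck) / sum(sel))
  }))
  list(n_truth = length(tk), n_called = length(ck), n_recovered = tp,
       sensitivity = if (length(tk) > 0) tp / length(tk) else NA_real_,
       precision = if (length(ck) > 0)
         sum(ck %in% tk) / length(ck) else NA_real_,
       by_k = by_k)
}
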