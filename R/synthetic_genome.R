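# Synthetic genome and gene-model generator.
#
# Emulates the study system at desk scale: one linear high-GC chromosome
# (GC ~ 72%), densely packed non-overlapping CDSs on both strands, and an
# optional terminal inverted repeat.  Defaults are the simulation's study
# conditions; mutation-load defaults are order-of-magnitude choices (no
# per-strain load is published for NTG/UV mutagenesis at this dose) and are
# documented in the methods vignette.

COG_LETTERS <- c("C", "E", "G", "H", "I", "J", "K", "L", "M", "O", "P",
                 "Q", "R", "S", "T", "U", "V")

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data module.  Defaults describe the
#' demo conditions: a 100-kb chromosome at 72% GC, two pools of 30
#' mutagenized strains, pooled depth 200x, and a 0.5% per-base miscall rate.
#'
#' @param genome_length chromosome length in bp
#' @param gc_content target GC fraction
#' @param n_genes number of non-overlapping CDSs to place
#' @param gene_length_range min/max CDS length in bp (rounded to codons)
#' @param tir_length terminal-inverted-repeat length in bp (0 = none)
#' @param n_strains_per_pool strains pooled per group
#' @param snv_rate per-bp per-strain substitution rate
#' @param indel_rate per-bp per-strain indel rate
#' @param indel_length_range min/max indel length in bp
#' @param transition_bias fraction of SNVs forced to be G:C->A:T
#'   transitions (the dominant NTG lesion)
#' @param mean_depth mean pooled read depth per site
#' @param base_error per-base miscall probability
#' @param seed integer seed; every generator derives its randomness from it
#' @return a `sim_config` list
#' @export
simulation_config <- function(genome_length = 1e5, gc_content = 0.72,
                              n_genes = 80, gene_length_range = c(300, 1500),
                              tir_length = 0, n_strains_per_pool = 30,
                              snv_rate = 2e-4, indel_rate = 2e-5,
                              indel_length_range = c(1, 6),
                              transition_bias = 0.70, mean_depth = 200,
                              base_error = 0.005, seed = 1) {
  cfg <- list(genome_length = as.integer(genome_length),
              gc_content = gc_content, n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              tir_length = as.integer(tir_length),
              n_strains_per_pool = as.integer(n_strains_per_pool),
              snv_rate = snv_rate, indel_rate = indel_rate,
              indel_length_range = as.integer(indel_length_range),
              transition_bias = transition_bias, mean_depth = mean_depth,
              base_error = base_error, seed = as.integer(seed))
  assert_that(cfg$gc_content > 0 && cfg$gc_content < 1,
              "gc_content must be in (0, 1)")
  assert_that(cfg$snv_rate >= 0 && cfg$indel_rate >= 0, "rates must be >= 0")
  assert_that(cfg$mean_depth > 0, "mean_depth must be positive")
  assert_that(cfg$base_error >= 0 && cfg$base_error < 0.25,
              "base_error must be in [0, 0.25)")
  assert_that(cfg$n_strains_per_pool >= 1, "need at least one strain per pool")
  structure(cfg, class = "sim_config")
}

# run expr under a fixed seed without clobbering the caller's RNG stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

rand_bases <- function(n, gc) {
  sample(c("G", "C", "A", "T"), n, replace = TRUE,
         prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# random CDS: ATG + sense codons + stop, composition near gc
rand_cds <- function(len_bp, gc) {
  n_codon <- len_bp / 3L
  inner <- n_codon - 2L
  codons <- character(inner)
  if (inner > 0) {
    raw <- paste0(rand_bases(inner, gc),
                  rand_bases(inner, gc), rand_bases(inner, gc))
    bad <- raw %in% STOP_CODONS
    while (any(bad)) {
      nb <- sum(bad)
      raw[bad] <- paste0(rand_bases(nb, gc), rand_bases(nb, gc),
                         rand_bases(nb, gc))
      bad <- raw %in% STOP_CODONS
    }
    codons <- raw
  }
  paste0("ATG", paste(codons, collapse = ""), sample(STOP_CODONS, 1))
}

#' Generate a synthetic genome with gene models
#'
#' Background sequence is i.i.d. with the configured GC; CDSs start with
#' ATG, end with a stop codon, contain no internal in-frame stop, and are
#' placed without overlap (and outside the terminal repeats when
#' `tir_length > 0`).  When `tir_length > 0` the terminal `tir_length` bp
#' are overwritten with the reverse complement of the initial `tir_length`
#' bp.  Deterministic given `config$seed`.
#'
#' @param config a [simulation_config]
#' @return list with `genome` ([genome_seq]) and `models` (gene-model data
#'   frame; every gene is a CDS with a random COG-style `category_label`)
#' @export
generate_genome <- function(config) {
  assert_that(config$genome_length >= 1000, "genome_length must be >= 1000")
  with_seed(config$seed, {
    L <- config$genome_length
    gc <- config$gc_content
    # gene lengths in whole codons (incl. start + stop)
    lens <- sample(seq(config$gene_length_range[1],
                       config$gene_length_range[2]), config$n_genes,
                   replace = TRUE)
    lens <- (lens %/% 3L) * 3L
    usable_lo <- config$tir_length + 1L
    usable_hi <- L - config$tir_length
    usable <- usable_hi - usable_lo + 1L
    if (sum(lens) > 0.9 * usable)
      stopf("infeasible packing: %d bp of genes into %d bp of genome",
            sum(lens), usable)
    # random non-negative gaps between genes summing to the slack
    slack <- usable - sum(lens)
    cuts <- sort(sample.int(slack + 1L, config$n_genes, replace = TRUE) - 1L)
    gaps <- diff(c(0L, cuts))
    starts <- usable_lo + cumsum(gaps) + c(0L, cumsum(lens))[seq_len(config$n_genes)]
    ends <- starts + lens - 1L
    strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)

    seq_chars <- rand_bases(L, gc)
    for (i in seq_len(config$n_genes)) {
      cds <- rand_cds(lens[i], gc)
      if (strand[i] == "-") cds <- revcomp(cds)
      seq_chars[starts[i]:ends[i]] <- strsplit(cds, "", fixed = TRUE)[[1]]
    }
    if (config$tir_length > 0) {
      tl <- config$tir_length
      seq_chars[(L - tl + 1L):L] <- comp_chars(rev(seq_chars[1:tl]))
    }
    genome <- genome_seq("chr1", paste(seq_chars, collapse = ""), "linear")
    models <- data.frame(
      gene_id = sprintf("gene%04d", seq_len(config$n_genes)),
      contig_id = "chr1", start = starts, end = ends, strand = strand,
      is_cds = TRUE,
      category_label = sample(COG_LETTERS, config$n_genes, replace = TRUE),
      product = NA_character_, stringsAsFactors = FALSE)
    list(genome = genome, models = models)
  })
}
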