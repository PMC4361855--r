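# Hand-constructed toy genome with fully known gene content, used by the
# annotator and comparison tests.  Layout (1-based, 6000 bp):
#   geneE  +   401.. 700  (100 codons)
#   geneA  +  1001..1600  (200 codons; codon 10 = CTG Leu, codon 132 = GCG Ala)
#   geneB  -  3001..3600  (200 codons)
#   geneC  +  4501..4800  (100 codons)
make_toy_genome <- function() {
  set.seed(99)
  L <- 6000L
  chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                  prob = c(0.14, 0.36, 0.36, 0.14))
  build_cds <- function(n_codons, special = list()) {
    inner <- rep("GCC", n_codons - 2L)
    for (nm in names(special)) {
      idx <- as.integer(nm) - 1L   # codon number -> inner index
      inner[idx] <- special[[nm]]
    }
    paste0("ATG", paste(inner, collapse = ""), "TAA")
  }
  put <- function(chars, start, cds, strand) {
    if (strand == "-") cds <- poolvar:::revcomp(cds)
    chars[start:(start + nchar(cds) - 1L)] <-
      strsplit(cds, "", fixed = TRUE)[[1]]
    chars
  }
  cdsE <- build_cds(100L)
  cdsA <- build_cds(200L, list(`10` = "CTG", `132` = "GCG"))
  cdsB <- build_cds(200L)
  cdsC <- build_cds(100L)
  chars <- put(chars, 401L, cdsE, "+")
  chars <- put(chars, 1001L, cdsA, "+")
  chars <- put(chars, 3001L, cdsB, "-")
  chars <- put(chars, 4501L, cdsC, "+")
  genome <- genome_seq("chr1", paste(chars, collapse = ""))
  models <- data.frame(
    gene_id = c("geneE", "geneA", "geneB", "geneC"),
    contig_id = "chr1",
    start = c(401L, 1001L, 3001L, 4501L),
    end = c(700L, 1600L, 3600L, 4800L),
    strand = c("+", "+", "-", "+"),
    is_cds = TRUE,
    category_label = c("C", "K", "E", "T"),
    product = NA_character_, stringsAsFactors = FALSE)
  list(genome = genome, models = models)
}

# deterministic single-base substitution partner
alt_base <- function(ref) c(A = "G", C = "T", G = "A", T = "C")[[ref]]

# minimal call row constructor
toy_call <- function(pos, ref, alt, vtype = "SNV", contig = "chr1") {
  data.frame(contig = contig, pos = as.integer(pos), ref = ref, alt = alt,
             vtype = vtype, depth = 100L, alt_count = 10L, var_freq = 0.1,
             alt_fwd = 5L, alt_rev = 5L, p_value = 1e-6, pool_id = "L",
             stringsAsFactors = FALSE)
}

# synthetic call sets with a prescribed amount of overlap, for set algebra
make_key_calls <- function(n, offset = 0L) {
  data.frame(contig = "chr1", pos = seq_len(n) + offset,
             ref = "A", alt = "G", stringsAsFactors = FALSE)
}

# one-row pileup site helper for call_site tests
toy_site <- function(depth, alt, alt_fwd = NULL, ref = "A", altb = "G",
                     mean_baseq = 30, pos = 100L) {
  if (is.null(alt_fwd)) alt_fwd <- alt %/% 2L
  ref_n <- depth - alt
  ref_f <- ref_n %/% 2L
  list(site = list(contig = "chr1", pos = pos, ref_base = ref,
                   depth = depth, mean_baseq = mean_baseq),
       alleles = data.frame(
         allele = c(ref, altb),
         fwd = c(ref_f, alt_fwd),
         rev = c(ref_n - ref_f, alt - alt_fwd),
         stringsAsFactors = FALSE))
}
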