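Package: poolvar
Title: Pooled-Mutant Variant Discovery and Pan-Genome Analysis for Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for bulk-segregant style variant discovery
    from pooled mutant libraries of a bacterial strain, and for pan-genome
    analysis across related species. Covers samtools-pileup ingestion with
    base- and mapping-quality filters, VarScan2-style pooled SNP/indel calling
    (minimum coverage, minimum variant frequency, strand filter, binomial
    error-model significance), gene-based functional classification of
    variants (synonymous/nonsynonymous/frameshift/stopgain and 300-bp
    near-gene windows), pool set algebra and category summaries, Fisher-exact
    category enrichment with Benjamini-Hochberg FDR, protein-family
    clustering with identity/coverage thresholds and
    core/dispensable/specific classification, and genome sequence statistics
    (GC content, GC skew, terminal inverted repeats). A synthetic-data module
    generates genomes, gene models, mutagenized strain pools and pooled
    pileups with a known truth set for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
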