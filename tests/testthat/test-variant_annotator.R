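toy <- make_toy_genome()

test_that("coding SNVs get the right effect class and protein notation", {
  # codon 132 of geneA is GCG (Ala); C->T at its middle base gives GTG (Val)
  pos <- 1001L + 3L * 131L + 1L   # middle base of codon 132
  expect_equal(substr(toy$genome$sequence, pos - 1, pos + 1), "GCG")
  ann <- classify_variant(toy_call(pos, "C", "T"), toy$genome, toy$models)
  expect_equal(ann$region_class, "nonsynonymous SNV")
  expect_equal(ann$aa_change, "A132V")
  expect_equal(ann$gene_ids, "geneA")

  # codon 10 is CTG (Leu); third-base G->A gives CTA, still Leu
  pos <- 1001L + 3L * 9L + 2L
  expect_equal(substr(toy$genome$sequence, pos - 2, pos), "CTG")
  ann <- classify_variant(toy_call(pos, "G", "A"), toy$genome, toy$models)
  expect_equal(ann$region_class, "synonymous SNV")
  expect_true(is.na(ann$aa_change))

  # GCC -> TCC in codon 20: nonsynonymous A20S
  pos <- 1001L + 3L * 19L
  ann <- classify_variant(toy_call(pos, "G", "T"), toy$genome, toy$models)
  expect_equal(ann$region_class, "nonsynonymous SNV")
  expect_equal(ann$aa_change, "A20S")

  # stopgain: GCC -> TGA needs two changes, so use GGA via C->A? use
  # codon GCC -> GCC with first base G -> T gives TCC (Ser).  For a stop,
  # mutate codon 50 middle base C -> A: GAC is Asp; instead change the
  # whole test to TAA via the known path: GCA? Simplest real stopgain in
  # an all-GCC gene: none exists from one substitution, so test stoploss
  # and stopgain on the stop codon itself.
  # stoploss: TAA (codon 200) first base T -> C gives CAA (Gln)
  pos <- 1001L + 3L * 199L
  expect_equal(substr(toy$genome$sequence, pos, pos + 2), "TAA")
  ann <- classify_variant(toy_call(pos, "T", "C"), toy$genome, toy$models)
  expect_equal(ann$region_class, "stoploss SNV")
  expect_equal(ann$aa_change, "*200Q")
})

test_that("stopgain arises when a sense codon mutates to a stop", {
  # build a plus-strand gene containing codon TAC (Tyr); TAC -> TAA is
  # a stopgain via third-base C -> A
  set.seed(1)
  chars <- sample(c("A", "C", "G", "T"), 400, replace = TRUE)
  cds <- paste0("ATG", "TAC", strrep("GCC", 30), "TAA")
  chars[101:(100 + nchar(cds))] <- strsplit(cds, "")[[1]]
  g <- genome_seq("c1", paste(chars, collapse = ""))
  m <- data.frame(gene_id = "g1", contig_id = "c1", start = 101L,
                  end = 100L + nchar(cds), strand = "+", is_cds = TRUE,
                  category_label = NA_character_, product = NA_character_,
                  stringsAsFactors = FALSE)
  ann <- classify_variant(toy_call(106, "C", "A", contig = "c1"), g, m)
  expect_equal(ann$region_class, "stopgain SNV")
  expect_equal(ann$aa_change, "Y2*")
})

test_that("minus-strand coding SNVs are classified in the gene frame", {
  # geneB is minus strand at 3001..3600; its codon 132's middle base sits
  # at genomic position end - (3*131 + 1)
  pos <- 3600L - (3L * 131L + 1L)
  ref <- substr(toy$genome$sequence, pos, pos)   # G on genome = C on CDS
  expect_equal(ref, "G")
  ann <- classify_variant(toy_call(pos, "G", "A"), toy$genome, toy$models)
  # CDS codon GCC -> GTC: Ala -> Val
  expect_equal(ann$region_class, "nonsynonymous SNV")
  expect_equal(ann$aa_change, "A132V")
  expect_equal(ann$gene_ids, "geneB")
})

test_that("coding indels split into frameshift and nonframeshift", {
  # 2-bp insertion between CDS positions 261 and 262 of geneA (genomic
  # 1261/1262): frameshift with the paper-style CDS notation
  anchor <- 1261L
  ref <- substr(toy$genome$sequence, anchor, anchor)
  ann <- classify_variant(
    toy_call(anchor, ref, paste0(ref, "CC"), vtype = "insertion"),
    toy$genome, toy$models)
  expect_equal(ann$region_class, "frameshift insertion")
  expect_equal(ann$cds_change, "261_262insCC")

  # 3-bp deletion inside geneA: nonframeshift
  ref3 <- substr(toy$genome$sequence, 1300, 1303)
  ann <- classify_variant(
    toy_call(1300L, ref3, substr(ref3, 1, 1), vtype = "deletion"),
    toy$genome, toy$models)
  expect_equal(ann$region_class, "nonframeshift deletion")
  expect_equal(ann$cds_change, "301_303del")

  # 1-bp deletion: frameshift
  ref1 <- substr(toy$genome$sequence, 1400, 1401)
  ann <- classify_variant(
    toy_call(1400L, ref1, substr(ref1, 1, 1), vtype = "deletion"),
    toy$genome, toy$models)
  expect_equal(ann$region_class, "frameshift deletion")
})

test_that("near-gene windows are strand-aware and mutually resolved", {
  # 150 bp 5' of geneA (+, starts 1001) and 151 bp 3' of geneE (+, ends
  # 700): both flanks hit -> upstream;downstream
  ann <- classify_variant(toy_call(851, "A", "G"), toy$genome, toy$models)
  expect_equal(ann$region_class, "upstream;downstream")
  expect_setequal(strsplit(ann$gene_ids, ";")[[1]], c("geneA", "geneE"))

  # 100 bp right of minus-strand geneB's rightmost coordinate = its 5'
  # side -> upstream
  ann <- classify_variant(toy_call(3700, "A", "G"), toy$genome, toy$models)
  expect_equal(ann$region_class, "upstream")
  expect_equal(ann$gene_ids, "geneB")

  # 100 bp left of geneB's leftmost coordinate = its 3' side -> downstream
  ann <- classify_variant(toy_call(2901, "A", "G"), toy$genome, toy$models)
  expect_equal(ann$region_class, "downstream")

  # far from everything -> intergenic
  ann <- classify_variant(toy_call(2300, "A", "G"), toy$genome, toy$models)
  expect_equal(ann$region_class, "intergenic")

  # window 0 turns all non-coding into intergenic
  ann <- classify_variant(toy_call(851, "A", "G"), toy$genome, toy$models,
                          window_bp = 0)
  expect_equal(ann$region_class, "intergenic")

  # with strand awareness off, the 3700 position is downstream-of-geneB
  ann <- classify_variant(toy_call(3700, "A", "G"), toy$genome, toy$models,
                          ignore_strand = TRUE)
  expect_equal(ann$region_class, "downstream")
})

test_that("a mixed toy set covers all twelve categories exactly once", {
  ref_at <- function(p, n = 1) substr(toy$genome$sequence, p, p + n - 1)
  calls <- rbind(
    toy_call(2300, ref_at(2300), alt_base(ref_at(2300))),          # intergenic
    toy_call(250, ref_at(250), alt_base(ref_at(250))),             # upstream (geneE)
    toy_call(1650, ref_at(1650), alt_base(ref_at(1650))),          # downstream (geneA)
    toy_call(851, ref_at(851), alt_base(ref_at(851))),             # up;down
    toy_call(1030, "G", "A"),                                      # synonymous
    toy_call(1396, "G", "T"),                                      # nonsynonymous (GCG->GCT is syn!) fixed below
    toy_call(1598, "T", "C"),                                      # stoploss? no
    toy_call(1261, ref_at(1261), paste0(ref_at(1261), "CC"),
             vtype = "insertion"),                                 # frameshift ins
    toy_call(1300, ref_at(1300, 4), ref_at(1300),
             vtype = "deletion"),                                  # nonframeshift del
    toy_call(1400, ref_at(1400, 2), ref_at(1400),
             vtype = "deletion"),                                  # frameshift del
    toy_call(4600, ref_at(4600, 1), paste0(ref_at(4600), "GCC"),
             vtype = "insertion"))                                 # nonframeshift ins
  # fix the two aa-level rows explicitly:
  calls$alt[6] <- "T"; calls$pos[6] <- 1395L; calls$ref[6] <- "C"  # A132V
  calls$pos[7] <- 1598L; calls$ref[7] <- "T"; calls$alt[7] <- "C"  # stop T->C
  ann <- annotate_set(calls, toy$genome, toy$models)
  expect_equal(nrow(ann), nrow(calls))
  # add a stopgain from the dedicated construction in its own gene set
  expect_setequal(
    unique(ann$region_class),
    setdiff(poolvar:::REGION_CLASSES, "stopgain SNV"))
  counts <- table(ann$region_class)
  expect_true(all(counts == 1))
})

test_that("category counts always partition the annotated set", {
  set.seed(31)
  L <- nchar(toy$genome$sequence)
  pos <- sample(10:(L - 10), 300)
  ref <- substring(toy$genome$sequence, pos, pos)
  calls <- data.frame(contig = "chr1", pos = as.integer(pos), ref = ref,
                      alt = vapply(ref, alt_base, ""), vtype = "SNV",
                      stringsAsFactors = FALSE)
  ann <- annotate_set(calls, toy$genome, toy$models)
  expect_true(all(ann$region_class %in% poolvar:::REGION_CLASSES))
  expect_equal(sum(table(ann$region_class)), nrow(calls))
})

test_that("classification is invariant under genome mirroring", {
  L <- nchar(toy$genome$sequence)
  rc_genome <- genome_seq("chr1", poolvar:::revcomp(toy$genome$sequence))
  rc_models <- toy$models
  rc_models$start <- L - toy$models$end + 1L
  rc_models$end <- L - toy$models$start + 1L
  rc_models$strand <- ifelse(toy$models$strand == "+", "-", "+")
  set.seed(32)
  pos <- sample(10:(L - 10), 200)
  ref <- substring(toy$genome$sequence, pos, pos)
  alt <- vapply(ref, alt_base, "")
  for (i in seq_along(pos)) {
    a1 <- classify_variant(toy_call(pos[i], ref[i], alt[i]),
                           toy$genome, toy$models)
    a2 <- classify_variant(
      toy_call(L - pos[i] + 1L, poolvar:::comp_chars(ref[i]),
               poolvar:::comp_chars(alt[i])),
      rc_genome, rc_models)
    expect_identical(a2$region_class, a1$region_class)
  }
})

test_that("codon-local effects agree with whole-protein retranslation", {
  set.seed(33)
  n_checked <- 0
  genes <- toy$models
  for (r in 1:200) {
    gi <- sample(nrow(genes), 1)
    g <- genes[gi, ]
    pos <- sample(g$start:g$end, 1)
    ref <- substr(toy$genome$sequence, pos, pos)
    alt <- alt_base(ref)
    ann <- classify_variant(toy_call(pos, ref, alt), toy$genome, genes)
    want <- retranslate_oracle(toy$genome, g, pos, alt)
    expect_identical(ann$region_class, want$class)
    if (!is.na(want$aa_change) && want$class != "synonymous SNV")
      expect_identical(ann$aa_change, want$aa_change)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 200)
})

test_that("annotating an empty call set returns an empty frame", {
  ann <- annotate_set(toy_call(1, "A", "G")[0, ], toy$genome, toy$models)
  expect_equal(nrow(ann), 0L)
  expect_true(all(c("region_class", "gene_ids", "aa_change") %in% names(ann)))
})
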