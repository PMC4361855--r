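#!/usr/bin/env Rscript
# Stage 3: pool set algebra and functional classification.
#
# Intersects the two pools' variant keys, keeps the group-specific sets,
# classifies each specific variant against the gene models (300-bp
# near-gene windows, bacterial code), and writes the category table with
# its roll-ups.

suppressMessages(library(poolvar))

out <- "results/compare"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genome <- read_fasta("scratch/sim/genome.fa")[[1]]
models <- read_gff3("scratch/sim/models.gff3")
calls_l <- read_vcf("results/calls/calls_L.vcf")
calls_h <- read_vcf("results/calls/calls_H.vcf")

cmp <- compare_pools(calls_l, calls_h)
cat(sprintf("pools: |L|=%d |H|=%d shared=%d (%.1f%% / %.1f%%)\n",
            cmp$n_low, cmp$n_high, cmp$n_shared,
            cmp$pct_shared_low, cmp$pct_shared_high))
cat(sprintf("group-specific: %d (L) and %d (H)\n",
            cmp$n_specific_low, cmp$n_specific_high))

ann_l <- annotate_set(calls_l[variant_key(calls_l) %in% cmp$specific_low, ],
                      genome, models)
ann_h <- annotate_set(calls_h[variant_key(calls_h) %in% cmp$specific_high, ],
                      genome, models)
s <- summarize_categories(ann_l, ann_h)
print(s$table, row.names = FALSE)
print(s$rollup, row.names = FALSE)

write.table(ann_l, file.path(out, "annotated_L_specific.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ann_h, file.path(out, "annotated_H_specific.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(s$table, file.path(out, "category_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(s$rollup, file.path(out, "category_rollup.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(affected_genes(ann_l, ann_h), file.path(out, "affected_genes.txt"))
cat(sprintf("%d genes carry amino-acid-changing variants\n",
            length(affected_genes(ann_l, ann_h))))
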