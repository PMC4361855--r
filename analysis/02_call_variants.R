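#!/usr/bin/env Rscript
# Stage 2: pooled variant calling.
#
# Reads each pool's pileup with the BaseQ>=20 / MAPQ>=10 filters, calls
# variants at minimum coverage 50, minimum variant frequency 0.03, strand
# filter on, binomial error-model significance 0.01, and writes one VCF
# per pool plus a recovery report against the planted truth.

suppressMessages(library(poolvar))

sim_dir <- "scratch/sim"
out <- "results/calls"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genome <- read_fasta(file.path(sim_dir, "genome.fa"))[[1]]
lens <- setNames(length(genome), genome$contig_id)
cfg <- caller_config()

for (pid in c("L", "H")) {
  pu <- read_pileup(file.path(sim_dir, sprintf("pool_%s.pileup", pid)),
                    min_baseq = cfg$min_baseq, min_mapq = cfg$min_mapq)
  calls <- call_pool(pu, cfg, pool_id = pid)
  write_vcf(calls, file.path(out, sprintf("calls_%s.vcf", pid)), lens)
  truth <- read_truth_tsv(file.path(sim_dir, sprintf("truth_%s.tsv", pid)))
  rec <- evaluate_recovery(calls, truth)
  cat(sprintf(
    "pool %s: %d calls; sensitivity %.3f (k>=3: %.3f), precision %.3f\n",
    pid, nrow(calls), rec$sensitivity,
    with(subset(rec$by_k, k >= 3), sum(n_recovered) / sum(n_truth)),
    rec$precision))
  write.table(rec$by_k, file.path(out, sprintf("recovery_%s.tsv", pid)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
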