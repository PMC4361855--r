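#!/usr/bin/env Rscript
# Stage 1: simulate the study system.
#
# One 100-kb linear chromosome at 72% GC with 80 non-overlapping CDSs, two
# pools of 30 mutagenized strains each ("L" and "H"), and a pooled pileup
# per pool at 200x with 0.5% per-base error.  Everything downstream reads
# the files written here.

suppressMessages(library(poolvar))

out <- "scratch/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- simulation_config(seed = 42)
gen <- generate_genome(cfg)
write_fasta(gen$genome, file.path(out, "genome.fa"))
write_gff3(gen$models, file.path(out, "models.gff3"))
cat(sprintf("genome: %d bp, GC %.1f%%, %d genes\n",
            length(gen$genome), gc_content(gen$genome),
            nrow(gen$models)))

for (pid in c("L", "H")) {
  mut <- mutagenize_pool(gen$genome, gen$models, cfg, pid)
  ps <- simulate_pileup(gen$genome, mut$truth, cfg,
                        seed = cfg$seed + 17L + match(pid, c("L", "H")))
  writeLines(ps$lines, file.path(out, sprintf("pool_%s.pileup", pid)))
  write_truth_tsv(mut$truth, file.path(out, sprintf("truth_%s.tsv", pid)))
  cat(sprintf("pool %s: %d planted variant keys (%d carried by >1 strain)\n",
              pid, nrow(mut$truth), sum(mut$truth$k > 1)))
}
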