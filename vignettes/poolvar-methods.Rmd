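---
title: "Models and methods behind poolvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind poolvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

poolvar re-implements, at desk scale, two linked analyses of a bacterial
producer strain: bulk-segregant-style variant discovery from pooled
mutant libraries, and pan-genome classification of its gene repertoire
against related species. This vignette is the package's account of the
models, the defaults, and the choices made where the design was open.

## The pooled design and its frequency model

Two groups of 30 mutagenized strains each are selected from the extremes
of a yield phenotype (low pool "L", high pool "H"). Equal amounts of
genomic DNA from each strain are pooled per group and sequenced, so a
variant carried by `k` of the `n = 30` strains segregates in its pool at
frequency exactly `k/n`. A singleton (`k = 1`) sits at 1/30 ≈ 0.0333 —
just above the caller's 0.03 frequency floor, which is why singleton
recovery is depth-limited while `k ≥ 3` variants (f ≥ 0.1) are recovered
essentially always at 200–400×.

The synthetic-data module emulates exactly this structure. It generates:

* one linear chromosome (default 100 kb) with i.i.d. base composition at
  a configurable GC (default 0.72, the high-GC regime of *Streptomyces*),
  densely packed non-overlapping CDSs (ATG start, stop at the end, no
  internal in-frame stop, length divisible by 3), and optionally a
  terminal inverted repeat;
* per-strain mutations: SNV and indel counts Poisson in the per-bp rates,
  with 70% of SNVs forced to be G:C→A:T transitions by default — the
  dominant NTG lesion — so the simulator is biologically flavored without
  claiming a measured spectrum. Defaults (`snv_rate = 2e-4`,
  `indel_rate = 2e-5` per bp per strain) are order-of-magnitude choices
  that give pool variant counts in the several-hundred range on the
  100-kb demo genome, comparable to a real pooled run; no per-strain
  mutational load is published for this mutagenesis regime, so these
  stay configurable and are never asserted;
* pooled pileups: per-site depth ~ Poisson(`mean_depth`), alt-supporting
  reads ~ Binomial(depth, `f(1−e) + (1−f)e/3`) with `e` the per-base
  miscall rate, strands assigned fairly, emitted in the 6-column samtools
  text dialect. Base qualities are uniform at the phred equivalent of
  `e` (Q23 for the default `e = 0.005`; Q40 when `e = 0`), so the
  caller's error model sees the rate that generated the data. Note this
  couples `e` to the BaseQ filter: an `e` above ~0.01 would emit
  qualities below the default BaseQ 20 floor and filter everything —
  intentional, since such data would be unusable in the real pipeline
  too.

What the simulator does *not* model: read-level artifacts (mapping error,
indel realignment ambiguity, strand bias from library chemistry, GC-
coverage coupling), linkage between nearby variants on the same strain
at the read level, and the yield phenotype itself (pools exist only as
labels). Passing tests therefore demonstrate the inference machinery is
correct under its stated model, not that the model captures every
failure mode of real pooled sequencing.

Two emission conventions are worth stating: reads within a pileup line
are grouped by symbol class (the format carries no meaningful read
order), and a deletion's `*` placeholders at subsequent positions are
treated by the reader as placeholders — excluded from allele counts and
from the recomputed depth.

## Pooled calling

Sites are read from the pileup with BaseQ < 20 and (when a 7th column is
present) MAPQ < 10 bases removed and depth recomputed. Per non-reference
allele the caller requires, with the defaults of the re-implemented
analysis:

* depth ≥ 50 (`min_coverage`);
* alt fraction ≥ 0.03 (`min_var_freq`), compared in exact integer
  arithmetic (`alt·10^6 ≥ depth·round(f·10^6)`) so a frequency exactly at
  the floor is called and no float-edge artifacts occur;
* one-sided binomial significance ≤ 0.01: `p = P(X ≥ alt)` with
  `X ~ Binomial(depth, e)` and `e = 10^(−meanBaseQ/10)`. The upstream
  tool's internal significance machinery is not fully specified, so the
  simplest defensible error-model null is used and exposed in
  `caller_config()`; 0.01 is that tool's documented default significance
  level;
* when the strand filter is on (default), at least 10% of alt reads on
  each strand — the documented behavior class of the original filter.

Indel alleles (`+SEQ`/`−SEQ`) annotate a subset of the reads counted
under their carrier base, so site depth equals the sum of base-allele
counts and an indel's frequency is carriers/depth. Multi-allelic sites
are evaluated per allele, because downstream set algebra keys on the
full (contig, pos, ref, alt) tuple. Indels are emitted anchored and
left-aligned (VCF convention) so keys are comparable across pools.

## Functional classification

Each variant receives exactly one category from the fixed vocabulary
(intergenic; upstream; downstream; upstream;downstream; synonymous /
nonsynonymous / stopgain / stoploss SNV; frameshift / nonframeshift
insertion / deletion). Precedence: CDS overlap wins; otherwise 300-bp
strand-aware windows on the 5′ and 3′ sides of genes decide the
near-gene classes, with "upstream;downstream" meaning proximity to two
different flanking genes (a variant inside one short gene's two windows
is resolved by the smaller distance). Whether the original 300-bp
windows were strand-aware is not knowable from the report;
strand-aware is the default here and `ignore_strand = TRUE` is provided.

Coding SNVs are translated with the bacterial genetic code (table 11),
comparing the reference and mutated codon; start-codon special-casing is
ignored for effect calling. Coding indels classify by length mod 3
alone — a frameshift that happens to retain a downstream stop is still
"frameshift", never "stopgain". A variant hitting several overlapping
CDSs takes the most severe effect (stopgain > stoploss > frameshift >
nonsynonymous > nonframeshift > synonymous) with all gene ids retained.

## Set algebra and reporting conventions

Variant identity is the normalized 4-tuple; allele-matching (not
position-only) intersection is the default, documented because the
original "common variants" wording does not say. Shared percentages are
rounded half-up to one decimal (the convention that reproduces the
printed 69.2/74.1/51.5). Pan-genome expansion rates and specific/core
ratios are *truncated* (2 and 3 decimals): truncation is the only rule
consistent with all four published values at once, e.g. a rate of
3105/1980 = 1.5682 printed as 1.56.

## Enrichment

Category over-representation is a one-sided hypergeometric upper tail
per category (k hits among n study genes, K labeled among N background
genes), BH-adjusted across categories. Genes with several labels count
once per label while N counts genes — the simplest model consistent with
multi-assignment of COG labels. The published analysis names both a
P-value cutoff of 0.01 and FDR-reported values without stating which
gated significance; the cutoff applies to FDR by default here and
`cutoff_on = "p"` is available.

## Pan-genome

Families are single-linkage connected components over similarity edges
passing identity > 50% and coverage > 70% — the minimal reading of
"were clustered", and the one an independent union-find oracle can
verify. Coverage is min(query, subject) by default, so families cannot
chain through domain-only hits; query-only and subject-only modes are
provided since the original convention is unknowable. Ingested BLAST
tabular hits are additionally gated at E ≤ 1e-5; the built-in
Smith–Waterman route (BLOSUM62, affine gaps 11/1) has no E-value, so a
raw score floor (default 50) replaces that gate — a deviation forced by
desk scale, and configurable. Core = present in every species of the
panel, specific = exactly one, dispensable = in between; without a
species tree no clade-aware sub-classification is attempted. Density
profiles use fixed 400-kb bins with per-class proportions summing to 1.

## Genome statistics

GC content excludes N from numerator and denominator. GC skew is
(G−C)/(G+C) per window, with empty windows emitting 0 and a flag. TIR
detection is an ungapped position-wise comparison of the prefix against
the reverse-complemented suffix — the repeat is a structural annotation,
not an alignment product — reporting the largest length whose running
mismatch fraction stays within the budget (default 0.01, since the
original tolerance is unstated), with a deterministic early stop after
100 consecutive mismatches.

## Problem sizes and determinism

Every generator is deterministic given its seed, and the end-to-end
bundle is byte-identical under a fixed config. The shipped tests and
the acceptance script run the pipeline at the demo conditions (20–100 kb
genomes, pools of 30, depth 200–400, ≥ 2000 planted sites for recovery
calibration, 5-species proteome panels of ~60 ancestral families) —
sizes chosen so the whole analysis reproduces on a laptop-class single
core in minutes while keeping Monte-Carlo bands tight enough for 3σ
checks.

## Known limitations

* Absolute call counts on real data are not reproducible desk-side: they
  depend on the sequenced libraries; only thresholds, set logic and
  report arithmetic are.
* The caller's p-value is an error-model tail, not a reimplementation of
  the original tool's internal statistic; decisions coincide wherever
  the published thresholds bind.
* Variants inside another variant's deletion footprint are dropped from
  the simulated truth with a message; their pileup evidence would be
  ambiguous in ways the original analysis never had to confront.
* The pan-genome route is exact Smith–Waterman, not a BLAST heuristic;
  at desk scale this is affordable and strictly more sensitive.
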