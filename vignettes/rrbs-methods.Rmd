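---
title: "Methods: simulation and analysis of RRBS methylomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and analysis of RRBS methylomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rrbspipe` implements an end-to-end reduced-representation bisulfite
sequencing (RRBS) workflow: an in-silico restriction digest of a reference
genome, a ground-truth read simulator, bisulfite-aware alignment,
per-cytosine methylation calling, windowed differential-methylation testing
with replicate consensus, and genomic annotation of the resulting regions.
The motivating design is a treatment-versus-control cell-line comparison
(for example, chronically exposed, malignantly transformed cells against
their parental line) with a small number of biological replicates per
condition. This vignette records the statistical model, the algorithmic
choices, and the reasoning behind the numerical defaults.

## 1. Reduced representation by double digestion

RRBS enriches for CpG-dense sequence by cutting the genome with
methylation-insensitive restriction enzymes whose recognition sites contain
a CpG, then size-selecting the fragments. `digest_genome()` performs an
in-silico double digestion with MspI (`C^CGG`) and TaqαI (`T^CGA`), both
cutting one base into the site. Cut positions from the two enzymes are
pooled (a union, as in a combined digestion reaction) and fragments are the
intervals between consecutive cuts, retained when their length falls in the
size-selection window, 40–350 bp by default. Both recognition sites are
reverse-complement palindromes, so a forward scan finds every site; a site
interrupted by `N` does not cut. Digestion is idempotent: no retained
fragment contains an internal cut site, a property the test suite checks on
simulated genomes.

## 2. The synthetic genome and methylome

`generate_genome()` samples chromosomes as i.i.d. nucleotides with a
background GC content of 0.40 and a CpG observed/expected ratio of 0.20,
obtained by rejecting a fraction of the CpG dinucleotides that would arise
by chance. This mimics the genome-wide CpG depletion of mammalian genomes
and — deliberately — keeps background sequence below the
Gardiner-Garden/Frommer island thresholds (length ≥ 200 bp, GC ≥ 0.5,
observed/expected CpG ≥ 0.6) used by `detect_cpg_islands()`, so that
detected islands are planted islands. Islands are planted as i.i.d.
GC-0.60 sequence without CpG depletion. The default density (120 islands of
600 bp per megabase) is exaggerated relative to real genomes so that small
simulations still contain enough island CpGs for windowed statistics; it is
a knob, not an estimate.

True methylation levels are drawn per cytosine from Beta distributions
parameterised by mean and concentration, `Beta(mu*kappa, (1-mu)*kappa)`
with `kappa = 20`: island CpGs are hypomethylated (`mu = 0.10`), background
CpGs hypermethylated (`mu = 0.75`), and non-CpG cytosines nearly
unmethylated (`mu = 0.01`), the canonical somatic pattern. Each biological
replicate redraws its level around the site baseline at concentration
`5*kappa`, giving realistic between-replicate variability. Differential
regions are planted by shifting the treated-condition mean of every CpG in
chosen 200-bp windows by a signed `delta` (clipped to [0, 1]);
`plan_dmrs()` picks grid-aligned windows that contain at least three
coverable CpGs and are purely island or purely background, so the planted
truth is recoverable in principle.

## 3. Read simulation

For each retained fragment, each strand mode (original-top, OT, and
original-bottom, OB) receives `Poisson(coverage)` reads starting at the
fragment's 5' end — the MspI/TaqαI end structure of directional RRBS
libraries. A read is the first 75 bases of the fragment (OT) or of its
reverse complement (OB); shorter fragments yield shorter reads, and when at
least three bases of room remain the sequencing adapter
(`AGATCGGAAGAGC...`) is read through into, exactly the artefact 3'-adapter
trimming must remove. Read-through shorter than three bases is not planted
because it sits below the resolution of the standard minimum-overlap-3
trimming rule: such a residue is indistinguishable from genomic sequence
and would make otherwise perfect reads unalignable, an artefact of the
simulator rather than of the chemistry.

Bisulfite chemistry is applied per cytosine of the read's strand: a
methylated cytosine survives as `C`; an unmethylated one converts to `T`
with the conversion probability (default 0.99, typical of current kits).
Methylation state is drawn per read from the sample's true level, and the
draw counts are recorded in a truth table alongside the fragment, strand
mode and offset of every read. Uniform sequencing errors (default 0.001)
and a low-quality 8-bp tail on a 5% subset of reads complete the model. All
randomness flows through R's RNG, seeded per stage and sample by
`stage_seed()`, so any master seed reproduces the study byte for byte.

## 4. Trimming and three-letter alignment

`trim_reads()` removes terminal `N`s, greedily trims 3' bases below the
quality floor (default Q3, phred+33 or phred+64), removes a 3' adapter
occurrence or terminal adapter prefix of at least three bases, and discards
reads shorter than 20 bp.

`align_reads()` implements the classical three-letter strategy: each
fragment is indexed twice, C→T for OT and G→A for OB, and the read is
compared under the corresponding reduction. Mismatches are counted between
the *original* read and *original* fragment, ignoring read-`T` against
fragment-`C` in OT mode (and the reverse-complement analogue in OB mode) —
so bisulfite conversion is never penalised while genuine mismatches,
including read-`A` against fragment-`G` in OT mode, are. Candidate
placements come from an exact pigeonhole seed index (a read with at most
`m` mismatches must contain an exact seed when split into `m + 2` parts);
reads shorter than the seeded regime fall back to brute force, so the
search is exhaustive. A read is reported `unique` only when the best
placement beats the second best by at least two counted mismatches, the
margin that makes single sequencing errors unable to flip the mapping;
otherwise it is `ambiguous`, and `unmapped` beyond the mismatch budget
(default 2). One consequence worth knowing: a fully converted read from a
reverse-complement-palindromic fragment matches both strand modes
perfectly and is inherently ambiguous.

## 5. Methylation calling and QC

`call_sites()` tallies, per cytosine and strand, `C`-evidence (methylated)
and `T`-evidence (unmethylated) from uniquely aligned reads; other bases
are sequencing errors and are ignored. The level is
`meth / (meth + unmeth)`, and sites with fewer than five informative reads
are dropped — below that depth a single read moves the level by ≥ 20
percentage points. Context (CpG/CHG/CHH) is classified from the two
downstream bases on the cytosine's strand; `merge_cpg = TRUE` pools the
symmetric CpG dyad onto the plus strand. Conversion efficiency is
estimated from CHH sites — nearly unmethylated in somatic mammalian cells,
so apparent CHH methylation is mostly failed conversion — as the
unmethylated fraction with a Wilson 95% interval, requiring at least 100
informative observations. The estimator inherits the true non-CpG
methylation level (about 1% by default) and any sequencing-error excess as
a downward bias; QC treats ≥ 0.98 as passing.

## 6. Differential methylation

Counts are compared per 200-bp origin-anchored window: within a window the
methylated and unmethylated CpG counts of each sample are pooled and tested
with a two-sided Fisher's exact test (sum of hypergeometric point
probabilities not exceeding the observed one, with a `1 + 1e-7` guard
against floating-point ties; a zero margin gives p = 1). Windows with fewer
than three shared retained CpGs are not tested. Benjamini–Hochberg
correction runs genome-wide across windows (`mode = "pooled"`, the
default); `mode = "per_site"` instead corrects per-site p-values within the
comparison and takes the window's minimum q, a more conservative variant.
A window is a DMR when p < 0.05, q < 0.01 and the absolute level difference
is at least 0.25. The q threshold is deliberately stricter than the p
threshold: thousands of windows are tested and the p cut alone would admit
dozens of null windows. An absolute — not relative — effect floor matches
how methylation differences act biologically; `site_differential()`
additionally flags "strong" single sites at |Δ| > 1/3.

With two replicates per condition, every control×treatment pair is tested
separately and `intersect_and_merge()` keeps windows called with the same
direction in *all* pairwise comparisons, then merges book-ended or
overlapping survivors, reporting the worst member q. Pairwise-then-
intersect was chosen over pooling replicates because it cannot be dominated
by a single aberrant replicate; its cost is conservatism, which the planted
-truth recovery tests quantify (sensitivity ≥ 0.9 at |Δ| = 0.5, 30×).
Fisher's test on pooled counts is itself conservative under between-
replicate biological noise; the suite's null-calibration test measures the
attained fraction of p < 0.05 windows on replicate-vs-replicate
comparisons and finds it close to, and slightly below, the nominal level.

## 7. Annotation

`assign_category()` classifies regions against gene models with precedence
promoter > exon > intron > intergenic, where the promoter is the ±1 kb
window around the strand-aware TSS (inclusive of the TSS base).
`category_distribution()` collapses exon/intron into "genic" for the
three-way promoter/genic/intergenic breakdown, overall and per direction.
DMRs map to genes via promoter or gene-span overlap, and
`overlap_stats()` scores the overlap between DMR genes and an external
gene list with a hypergeometric upper-tail p-value. Categories are exactly
invariant under coordinate mirroring with strand flips, which the tests
exploit as a symmetry oracle.

## 8. Running the whole study

```{r pipeline, eval = FALSE}
library(rrbspipe)
cfg <- pipeline_config(
  out_dir = "rrbs_run",
  sim = sim_config(seed = 1L),
  log_level = "info")
run <- run_pipeline(cfg)
run$consensus          # consensus DMRs
run$categories         # promoter/genic/intergenic breakdown
run$qc                 # conversion + coverage QC per sample
```

`run_pipeline()` writes every stage's outputs (FASTA, BED, FASTQ,
alignment tables, cytosine reports, bedGraphs, DMR tables, a Markdown
report and a JSON summary) plus a manifest with per-stage counts that is
written even when a stage fails. An end-to-end reproduction with headline
numbers is in `scripts/acceptance.R`:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```
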