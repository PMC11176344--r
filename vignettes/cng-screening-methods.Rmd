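---
title: "Methods: screening unstable CNG repeat loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening unstable CNG repeat loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cngscreen)
```

## The screening problem

Trinucleotide repeat expansions — most prominently the CNG class (CAG,
CCG, CGG, CTG, GCC) — cause a family of neurodegenerative disorders
including the spinocerebellar ataxias. Known pathogenic loci were found
one at a time; `cngscreen` implements the complementary heuristic: scan a
reference genome for *every* exact CNG repeat run, keep the loci whose
length and functional location resemble known disease repeats (long runs
in coding sequence or untranslated regions), and then measure allele-length
variability at those loci in a genotyped population. Loci that are highly
polymorphic in healthy controls are the expansion-prone candidates worth
screening in patient cohorts.

The pipeline has four computational stages, each usable on its own:

1. **Repeat scan** (`scan_sequence()`, `scan_fasta()`) — maximal exact
   tandem runs per motif.
2. **Region annotation** (`annotate_loci()`) — one of 13 functional
   labels per locus from a transcript model.
3. **Prioritization** (`summarize_matrix()`, `select_candidates()`) —
   length-group bookkeeping and the candidate rule.
4. **Variability analytics** (`locus_summary()`, `classify_stability()`,
   `compare_cohorts()`) — allele statistics, heterozygosity, stability
   classes and nonparametric cohort comparison.

## Repeat detection model

A *maximal run* of motif $u$ (length $L$) is an interval containing $k$
contiguous exact copies of $u$ that cannot be extended by one further
full copy on either side. Partial copies never count: `CAGCAGCA` holds
two units. Runs are detected per motif with a greedy regular expression
(`(CAG)+` and so on), which reports exactly the maximal runs provided the
motif is *primitive* (not a power of a shorter unit). For primitive
motifs two maximal runs of the same motif can never overlap — an
occurrence of a primitive word inside its own square only exists at the
trivial phases — so the greedy scan, which reports leftmost
non-overlapping matches, is complete. `repeat_motif()` therefore rejects
non-primitive units such as `AAA` (use `A`); all CNG units are primitive,
so this restriction costs nothing in scope. The declarative
`brute_force_oracle()` re-derives the same set by exhaustive substring
testing and is used throughout the tests as an independent check.

Defaults and their reasoning:

* `min_units = 4` — the classical screening floor for trinucleotide
  loci; shorter runs are ubiquitous and uninformative.
* Case-insensitive scanning — reference genomes arrive soft-masked, and
  genome-wide repeat totals include masked regions; masking is a
  repeat-annotation artifact, not sequence absence. `case_sensitive =
  TRUE` is available for masking-aware experiments.
* `N` (and every IUPAC ambiguity code) splits a run; the two flanks are
  evaluated independently against `min_units`. With
  `break_on_ambiguous = FALSE`, `N` instead matches any motif base.
* Frame-shifted overlaps: a CCG run of $k$ units contains a GCC run of
  $k-1$ units. Both are reported by default (each motif is an
  independent query, and published per-motif tallies count them
  separately); `dedup_frame_shifts = TRUE` suppresses any run wholly
  contained in a longer run of a rotationally equivalent motif. The
  published genome-wide total does not state which convention it used,
  which is why both are provided.
* Coordinates are 0-based half-open internally; writers also emit
  1-based inclusive columns, the convention of printed locus tables.

## Annotation model

Each locus receives exactly one of 13 labels: Coding, Splicing,
Exonic;Splicing, 5'UTR, 3'UTR, 5'UTR;3'UTR, Intronic, ncRNA-Exonic,
ncRNA-Intronic, Upstream, Downstream, Upstream/Downstream, Intergenic.
Per transcript: CDS overlap gives Coding; overlap with the first
`splice_window` intronic bases of an internal exon boundary gives
Splicing (together with an exonic overlap, Exonic;Splicing); exonic
overlap outside the CDS gives the strand-aware UTR labels; otherwise a
locus inside the span is Intronic, with the ncRNA variants for noncoding
transcripts. Outside the span, a gap smaller than `upstream_window` on
the transcription-start side gives Upstream, on the far side Downstream
(gap 0 = adjacent).

Conflicts across transcripts are resolved by a fixed precedence
(`region_precedence()`): exonic > intronic > flanking > intergenic, with
the combined labels (Exonic;Splicing; 5'UTR;3'UTR from a 5'UTR and a
3'UTR hit on different transcripts; Upstream/Downstream from opposite
flanks) outranking their components. The windows default to 1,000 bp
(upstream/downstream) and 2 bp (splicing) — the conventional gene-based
annotation defaults — and are configurable because published screens
rarely state them. Precedence makes annotation order-independent and
monotone: adding a transcript can only move a label up.

Both common gene-model dialects are read and normalized: GFF3 (1-based
inclusive) and refGene-style tables (0-based half-open starts); the
reader logs which dialect it detected, since silent dialect confusion is
the classic off-by-one source in this kind of tool.

## Prioritization

Reference repeat lengths are grouped as Group1 (4–6 units), Group2 (7–9)
and Group3 (≥ 10). `summarize_matrix()` tallies loci per (group, motif,
label) with recomputed totals — every locus lands in exactly one cell,
so the grand total always equals the locus count. The candidate rule
keeps loci with ≥ 10 units located in coding sequence or UTR. Two
published ambiguities are exposed as flags rather than resolved
silently: whether the combined exonic labels count as CDS/UTR
(`combined`, default yes — they are exonic) and whether the length rule
is ≥ 10 or > 10 (`strict_gt`, default ≥ 10, consistent with candidate
tables that contain exactly-10-unit reference repeats).

## Variability analytics

Fragment-analysis output is converted with
`units = round((fragment − flank) / unit_len)`; residuals above 1 bp
trigger a warning since they usually indicate a wrong flank length.
Statistics are computed over the allele multiset (two alleles per
sample), so the chromosome count is twice the genotyped sample count and
unequal chromosome counts across loci simply reflect assay dropout.
Conventions: sample SD ($n-1$); mode ties break toward the smaller
allele; even-sized medians average the central pair. The heterozygosity
index (HI) is *observed* heterozygosity — the fraction of samples with
two distinct alleles; expected heterozygosity $1 - \sum_i p_i^2$ is
reported alongside under its own name, never conflated.

The stability rule classifies a locus by its variability span
$\max - \min$ (repeat units) in the cohort: span ≥ 7 is polymorphic,
open-ended upward. Against the bundled published control ranges this
rule reproduces 51 of 52 published calls; the one exception (RAI1,
range 11–17, span 6, published as polymorphic) is an internal
inconsistency of the published set, so an explicit per-locus override
list (`reference_override()`) reproduces the published set verbatim
rather than bending the rule.

Cohort comparison uses Wilcoxon tests with midrank ties. Because the
standard implementation refuses exact p-values under ties — and repeat
lengths are heavily tied — the exact conditional null given the observed
midranks is computed here directly: the rank-sum null by subset-sum
dynamic programming over doubled midranks, the signed-rank null by a
generating-function product over sign flips. The exact path is taken
when the smaller side has ≤ 25 observations (counts stay below $2^{53}$,
so double arithmetic is exact); larger samples use the normal
approximation with tie-corrected variance and continuity correction.
Unpaired mode (`rank_sum`) compares allele multisets at one locus;
paired mode (`signed_rank`) compares per-locus summary values (default:
the modal allele) across a locus panel, both provided because published
usage of "the Wilcoxon signed rank test" on such data is ambiguous
between the two.

## Synthetic data: what it emulates and what it does not

The generators exist so every stage is testable offline with known
truth.

* `make_genome()` plants exact maximal runs on uniform random
  background. Each run is flanked by unit-length blocks of a base
  absent from its motif, which provably prevents extension of the run
  or of any rotation of it; background windows that by chance contain a
  scannable run are redrawn (rejection sampling), so the truth table is
  *exhaustive* — the property that makes exact precision/recall tests
  meaningful. Rotation-derived runs inside planted runs (GCC inside
  CCG) are computed analytically into the expected table.
* `make_gene_model()` builds one isolated transcript (two for
  5'UTR;3'UTR) per planted locus from fixed interval templates chosen
  so the default-window annotation provably returns the requested
  label, and verifies that no transcript (plus window) reaches any
  other planted locus.
* `make_cohort()` draws two alleles per sample independently from a
  per-locus spectrum — Hardy–Weinberg random mating — and reports
  expected heterozygosity per locus as truth.

All generators are bit-reproducible for a fixed seed. What the
synthetic data does **not** emulate: base-composition and repeat-density
structure of real genomes, impure/interrupted repeats, overlapping real
transcript architectures, genotyping stutter and allele dropout,
population structure and inbreeding (no departure from random mating).
Passing the synthetic suite therefore demonstrates algorithmic
correctness on clean inputs, not robustness to assay artifacts.

## Problem sizes and numerical choices

The shipped tests run the scanner against the brute-force oracle on 100
random 300-mers, recover planted loci on genomes of tens of kilobases,
check HI convergence at 2,000 simulated samples (a 3-binomial-SE band),
and calibrate the rank-sum type-I error over 100 identical-spectrum
cohort pairs of 200 samples — sizes chosen so the whole suite exercises
every contract in well under a minute of compute while keeping the
statistical bands meaningful. A full-genome reproduction (the published
run found 15,069 loci in hg19 and 52 candidates) requires the hg19 FASTA
and a refGene snapshot and streams record-by-record through
`scan_fasta()`; the bundled published tables make the downstream
bookkeeping checkable without that download, and the convention toggles
above are provided because the published run does not pin its
conventions.

Degenerate inputs are handled explicitly: empty sequences and empty
spectra are rejected or return empty tables with warnings as documented;
zero paired differences are dropped before signed-rank testing;
single-allele spectra are valid (HI = 0 by construction). Determinism is
a contract: the pipeline writes atomically and re-running with identical
inputs, configuration and seed produces byte-identical outputs and
manifest — the manifest deliberately carries no wall-clock timestamps
for this reason.

## Known limitations

* Only exact contiguous repeats are detected; interrupted repeats —
  which matter for some expansion loci — are out of scope by design.
* Annotation reproduces conventional gene-based precedence; reproducing
  a specific published candidate list also requires that study's exact
  transcript snapshot.
* The stability threshold (span ≥ 7) is a screening heuristic, not a
  population-genetic model of mutability.
* Catalog comparison trusts external allele counts as given; no
  correction for the short-read undercalling that makes public STR
  catalogs conservative at long alleles.
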