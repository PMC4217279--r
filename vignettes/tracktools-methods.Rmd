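---
title: "Methods: mapping classification, RNA-seq analyses and the Express test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping classification, RNA-seq analyses and the Express test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracktools)
```

This vignette documents the models and procedures implemented in
`tracktools`, the parameters that matter, the numerical conventions at the
corners, and the design choices that were genuinely open — together with
what the synthetic-data generator does and does not emulate, and hence what
a passing test suite does and does not show about real data.

## Coordinates and containers

All coordinates are 1-based, fully closed intervals on the forward strand;
feature strand is carried separately, so `start <= stop` always holds.
0-based half-open conversion happens only at the BAM boundary. Every
user-facing function takes and returns tibbles so analyses compose with the
pipe; a reference genome is a light S3 container of contig sequences plus a
feature table.

## Mapping classification

For each read (mates counted separately), the number of its alignment
records and the minimum edit distance across them are tabulated from the
file itself — not from aligner hint tags — so the classification is
aligner-independent and verifiable. "Mismatches" is operationalised as the
alignment's edit distance (substituted + inserted + deleted bases), taken
from the standard `NM` tag when present and recomputed against the
reference otherwise; a Perfect Match therefore requires a gapless,
substitution-free alignment. Secondary and supplementary records count
toward the mapping count; duplicate-flagged records are kept. Labels:

* `PERFECT` iff edit distance 0;
* `BEST` iff the record attains its read's minimum (but nonzero) edit
  distance;
* `COMMON` otherwise,

with the *query* semantics cumulative (`PERFECT` ⊆ `BEST` ⊆ `COMMON`), so
class-filtered coverage nests at every position. `single_best_match` is set
on the unique record attaining the minimum, when it is unique. Classified
tracks persist as coordinate-sorted indexed BAM with three custom tags
(`Yc` class character, `Yn` mapping count, `Ys` single-best flag); re-opening
a track never re-derives the classification.

## Read-pair classification

A *mapping pair* is the full set of alignments of a sequenced pair's two
reads. Pair distance is the **outer distance**: rightmost aligned base of
the rightmost mapping minus leftmost aligned base of the leftmost mapping,
plus one (the fragment length). A pairing is *perfect* when its orientation
matches the library (`fr` innies by default, configurable to `rf`/same-strand)
and its distance lies within `expected_distance * (1 ± deviation)`.

With one mapping per mate the lone combination is emitted as a Perfect or
(on any geometry violation) Distorted pair. With more than two mappings,
all perfect-geometry pairings are emitted without reusing any mapping;
among correctly oriented pairings *below* the interval, one per genomic
region — the one closest to the interval, i.e. with the largest distance —
becomes a Distorted pair; everything left is a Single Mapping, and
wider-than-interval combinations never pair in the multi-mapping case.
A *region* is a connected neighbourhood of candidate pairings (spans within
the outer perfect bound of each other, or sharing a mapping).

One design point was genuinely open: how to select the perfect-geometry
pairings. A purely greedy scan ordered by mapping-class preference can
*lose* a perfect pair when a widened deviation adds a better-scoring
candidate that blocks two previously chosen ones — violating the natural
monotonicity requirement that more tolerance never yields fewer perfect
pairs. The package therefore selects perfect pairs by maximum-cardinality
bipartite matching (weights encode, strictly below the cardinality term,
the Perfect > Best > Common class preference and distance closeness as
tie-breaks). Cardinality maximisation is monotone under edge addition by
construction, and the weight ordering keeps the classical preference
deterministic.

## SNP and DIP detection

At every position, each alternative allele is counted over the mappings
admitted by the class filter: substituted base calls, insertions anchored
to the reference base they follow, deletions keyed by their first deleted
base. Two conjunctive thresholds gate a call: frequency
`100 * count / total >= min_variation_percent` and
`count >= min_mismatch_count`. The denominator is the *eligible* coverage —
reads of the admitted classes whose alignment covers the base — not the raw
file depth; for deletions it is the deletion-spanning coverage (aligned or
deleted at that base), a convention the per-allele records document
explicitly. `N` read bases leave both numerator and denominator.
Multi-allelic positions emit one record per passing allele, which exports
cleanly to VCF (indels anchored in the standard way). Strand-specific
counting is off; per-strand supporting counts are reported as diagnostics.

For substitutions inside a CDS, the reference and alternative codon are
computed in the CDS frame — on the reverse complement for minus-strand
CDS — and translated with a selectable NCBI code (default table 11). CDS
whose length is not divisible by 3 are skipped with a warning rather than
mistranslated.

## TSS detection and automatic parameter estimation

Detection scans, per strand and in transcription direction, all n−1
neighbouring position pairs of a contig. Position p is a candidate when
both criteria hold:

* read starts at p (5′ ends: leftmost base of plus-strand mappings,
  rightmost of minus-strand) `>= min_read_starts`;
* percent coverage increase from the upstream neighbour u (p−1 on plus,
  p+1 on minus), `100 * (cov[p] − cov[u]) / max(cov[u], 1)`,
  `>= min_percent_increase`.

The two criteria balance: the increase criterion rejects positions inside
already highly covered regions where absolute read starts alone would fire.
For zero upstream coverage the denominator is clamped to one, so the
increase reduces to `100 * cov[p]` and the read-start criterion dominates —
the package's resolution of the low-coverage corner, chosen so
zero-background starts stay detectable without dividing by zero. Within
each 3 bp window only the best-scoring position is reported (score = read
starts; ties resolve to the 5′-most position), absorbing stepwise coverage
increases.

**Auto-estimation.** Both thresholds can be estimated from the track
itself as upper 0.0025-quantile cutoffs of the empirical distributions of
(i) per-position read-start counts and (ii) per-pair percent increases,
pooled over both strands of all contigs. On discrete count data the naive
order-statistic rule (value at rank ⌈(1−q)·n⌉, admission by `>=`) can admit
far more than the intended mass: with low coverage most positions tie at
small integers, and the rank value collapses to 0 or 1. The package
therefore uses a tie-aware cutoff: the smallest observed value `v` with
`#{x >= v} <= ceiling(q * n)`. This reproduces the rank construction
whenever ties don't straddle the boundary and guarantees analytically that
each criterion admits at most 2.5 positions per kb of scanned positions at
the default mass — the stated design intent of the 0.0025 choice (≈2.5
candidate genes per kb against the ≈1 gene/kb gene density of prokaryotic
genomes). A degenerate all-equal distribution admits *no* position (no
value is in the upper quantile of all others); `min_read_starts` is
additionally floored at 1. Whether to pool strands was open; pooling is the
default and matches the per-genome-position reading of the distribution.

Each reported TSS is associated with the nearest same-strand feature whose
5′ end lies within the 1000 bp association window (`annotated-start`,
covering both novel verification and correction of annotated starts).
Unassociated TSS are `novel` when inside a same-strand feature (an internal
start), `cis-antisense` when inside an opposite-strand feature, and
`trans-encoded` when intergenic — precedence in that order, the package's
operationalisation of categories that are named but not defined
operationally elsewhere. For all three a novel transcript is suggested from
the TSS to the last position with coverage at or above
`transcript_end_coverage` (default 1).

Defaults: `collapse_window` 3 bp, `association_window` 1000 bp,
`quantile_mass` 0.0025, class filter `BEST` (Perfect + Best coverage;
Common mappings add repeat noise to start counts).

## Operon detection

Neighbouring same-strand genes join an operon when the number of uniquely
mapped reads (mapping count 1 — multi-mapped reads are never spanning
evidence) overlapping at least one base of both genes is **strictly
greater** than the threshold; qualifying adjacent pairs chain transitively
into maximal operons. The strict inequality follows the definition of the
threshold as a noise floor; the package applies the same strictness to the
fallback, where a pair whose intergenic gap is wider than the track's
median read length may instead qualify by its minimum gap coverage. Gene
rows are preferred over CDS rows when both annotate the same locus.

## Quantification and coverage analyses

`quantify_features()` counts, per feature, the admitted reads overlapping
it (each read once per feature) and derives
`RPKM = count * 1e9 / (total_mapped_reads * feature_length_bp)`; RPKM and
raw-count filters are closed intervals. `feature_coverage()` reports the
share of feature bases covered at or above a floor and partitions features
into covered/uncovered at a percentage threshold. `coverage_regions()`
reports maximal runs below (`<`) or at/above (`>=`) an absolute or
mean-multiple threshold; for a fixed threshold the two modes partition the
contig exactly.

## The Express test

For conditions A and B with n and m replicates and per-region counts, the
test computes per region the mean and the sample variance (divisor w−1),
the two ratios mean_A/mean_B and mean_B/mean_A, and the confidence

> C = −log₁₀[ ½ ( var_A/mean_A + var_B/mean_B ) ]

Conventions at the corners, applied exactly as stated:

* a zero mean in a ratio's denominator is replaced by one;
* C = −1 whenever a condition mean is zero (a sentinel, not a value of the
  formula);
* both variances zero at positive means gives −log₁₀(0): reported as `Inf`,
  the documented maximal-confidence sentinel (serialized as `"inf"`) — a
  case the formula leaves open;
* single-replicate conditions are allowed: variance 0 plus an explicit
  warning flag on every result row, rather than refusal.

Normalization (optional; basis = all regions or a user list such as
housekeeping genes) computes per-sample factors
`mean(basis totals) / basis total(sample)`; normalized counts are raw
counts times the factor, so basis totals equalise across samples. Factors
use count sums, not means — means would give identical ratios; sums are
documented for reproducibility. When normalization is on, *all* statistics
including C use normalized (generally non-integer) counts — the coherent
reading of normalizing "the results". MA values: M = log₂(mean_B/mean_A)
with the zero-denominator convention, A = ½·log₂(mean_A·mean_B) with zero
means replaced by one. High ratio and high C together flag differential
candidates; the Express test deliberately performs no statistical test and
reports no p-values — count-model tools (e.g. DESeq2, edgeR) are the
follow-up for inference.

## The synthetic-data generator

The simulator emits pre-aligned SAM rather than FASTQ: the package's
contract starts at mapped reads, so fixtures do too. A single seeded RNG
wrapper makes every output a pure function of its seed. What each preset
emulates:

* *resequencing*: error-free reads at uniformly random positions and
  strands; planted substitutions/insertions/deletions are carried, with
  consistent CIGAR/sequence/edit distance, by the stated percentage of the
  reads able to carry them. Reads that would start inside deleted bases, or
  with too little room to align an insertion, start just past the event —
  so a 100% planted frequency is observed as exactly 100%. Planted variants
  must be at least one read length apart.
* *rnaseq-5prime*: a sharp pileup of k read starts at each planted TSS over
  a smooth background of evenly tiled transcript-body reads (tile spacing
  `read_length / depth` per strand), so background positions carry at most
  one read start each.
* *paired*: forward-reverse pairs with outer distances drawn inside the
  perfect interval; a planted fraction is distorted, half by a too-small
  distance and half by wrong orientation.
* *multi-mapped*: several placements per read with asserted edit
  distances (the `NM` tag is authoritative; base-level sequence consistency
  is not maintained for secondary placements).
* *counts*: negative-binomial two-condition count tables with planted fold
  changes.

Not emulated: sequencing errors beyond the planted events, platform error
profiles, stochastic start-position noise under the 5′ protocol, GC or
mappability bias, chimeric reads. Consequently, exact-recovery results on
these fixtures demonstrate the correctness of the algorithms under their
stated assumptions — not calling performance on noisy real libraries, where
thresholds trade sensitivity against precision and stepwise TSS increases
or low-frequency variants can fall below the automatic cutoffs.

## Problem sizes and numerical checks

The test suite exercises the full pipeline at the scale of a 100 kb genome
at 50× depth (10⁵ reads) for planted-variant, TSS and operon recovery, 10⁴
multi-mapped reads for the classification invariants, 10³ simulated read
pairs for pair-semantics and fraction recovery, 10³ random inputs against a
brute-force arithmetic oracle for the Express test (10⁻¹⁰ relative
tolerance), and 100 random parameterisations against an all-pairs
brute-force TSS scan on sub-10 kb tracks — sizes chosen so the whole suite
runs in a few minutes on one core while still exceeding the regimes where
the algorithms' asymptotics and tie-handling matter.

## Known limitations

* GenBank/EMBL parsing targets the common prokaryotic flat-file subset;
  `join()` locations collapse to their span with a warning (compound
  eukaryotic gene models are out of scope). GFF2 is parsed as a best-effort
  dialect of GFF3, as GFF2 itself is only loosely specified.
* Multi-contig references are accepted and analysed per contig, but pair
  candidates spanning two contigs are not formed.
* The variant caller is a threshold caller: no genotype likelihoods, no
  somatic/population model.
* Overlapping gene/CDS annotations are kept as-is on import; analyses
  select by feature type (operon detection prefers gene rows, effect
  annotation uses CDS rows).
* The CLI takes parameters as flags only; every run writes a
  `manifest.json` from which it can be reproduced.
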