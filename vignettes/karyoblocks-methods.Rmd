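---
title: "Methods: ancestral-block painting, karyotype assembly, and companion analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ancestral-block painting, karyotype assembly, and companion analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(karyoblocks)
```

`karyoblocks` lifts a fragmented crucifer scaffold assembly to
chromosome scale using comparative information instead of a genetic
map. This vignette explains each model and procedure, the parameters
that matter, the numerical conventions, and what the synthetic-data
tests do and do not demonstrate about real data.

## The block model and its assumptions

Crucifer (Brassicaceae) genomes can be described as rearrangements of
24 conserved ancestral chromosomal blocks, labelled A–X, each defined
by a syntenic set of *A. thaliana* genes. The package's central
assumptions are:

1. **Block membership is authoritative input.** Each reference gene
   belongs to exactly one block with a fixed rank (ancestral index)
   inside it. Genes that map equally well to two blocks are not
   modelled; a wrong placement is treated as noise for the painter to
   absorb, not re-assigned.
2. **Scaffolds are never split.** An observed conflict with the
   karyotype may be real lineage-specific rearrangement, so conflicts
   are reported for human review rather than resolved by breaking
   sequence.
3. **The karyotype is input, not inferred.** The per-chromosome signed
   block order and centromere position come from cytogenetic evidence
   (chromosome painting); the package arranges scaffolds to fit it and
   scores the disagreements.

## Painting (`paint_scaffolds`)

Genes placed on a scaffold are scanned in coordinate order and
segmented into maximal runs of one block label. Two knobs control the
noise tolerance:

- `min_run` (genes, default **3**): runs shorter than this are
  discarded, so single-gene transpositions or mismappings cannot
  create blocks.
- `max_interleave` (genes, default **2**): up to this many consecutive
  foreign-label genes inside a run are absorbed (counted, logged, not
  made members). This soaks up isolated mislabelled genes without
  fragmenting a true segment.

Segment orientation is the sign of Kendall's tau between scaffold
order and ancestral index over the member genes. A rank statistic is
robust to a few mismapped genes where a naive first-vs-last comparison
is not; `|tau| < 0.5` yields `"?"` (insufficient evidence) rather than
a guess. The smoothing rules real pipelines apply here are rarely
published, so these two knobs are deliberately explicit and tunable.

## Karyotype assembly (`match_scaffolds`)

Scaffolds are processed largest-first (by painted gene count),
mirroring the manual practice of anchoring the big scaffolds first; in
a real crucifer assembly the top ~25 scaffolds carry nearly all of the
sequence, and largest-first makes the procedure deterministic. Each
scaffold's ordered block labels are matched, forward or reversed, to
the longest exact contiguous run in one chromosome's block order.
Orientation is decided by, in increasing priority:

1. match direction (multi-block scaffolds);
2. agreement between segment tau-signs and karyotype block signs
   (single-block scaffolds);
3. **satellite-terminal evidence**, which overrides both: a
   centromeric-satellite-bearing terminus must face the centromere.
   When the override changes the answer the disagreement is logged as
   an `orientation_conflict` — orientation evidence from centromeric
   repeats outranks gene-order evidence, but the conflict is never
   silent.

Two scaffolds may legitimately share one boundary block position (a
block split across scaffolds); an overlap of two or more positions, or
a shared position interior to either range, means two scaffolds claim
the same unique spot — the smaller one is binned unplaced with an
`order_conflict`. Scaffolds sharing a block are ordered inside it by
their segment's mean ancestral index, read in the block's sign
direction.

Pseudomolecules join scaffolds with 100-bp N gaps (AGP type `U`,
linkage `no` — the AGP convention for gaps of unknown size). All
internal coordinates are 0-based half-open; conversion to 1-based
inclusive happens only at AGP export, so interval arithmetic is
unambiguous everywhere else.

## Satellite detection (`find_arrays`)

Period estimation is base-match autocorrelation: for candidate period
p, the score is the fraction of positions i with base(i) = base(i+p).
A suffix-tree tandem-repeat finder would be more general, but for
high-copy centromeric satellites autocorrelation is simple, exactly
testable, and sufficient. Conventions:

- `min_period`/`max_period` default **50/500 bp**, bracketing the
  ~177-bp CentO satellite class with a wide margin.
- `match_threshold` default **0.8**: with ~1% per-copy divergence two
  copies agree at ~98% of positions, while unrelated sequence agrees
  at ~25%, so 0.8 separates the two regimes with a wide margin.
- Harmonics: multiples of the true period score equally well, so the
  smallest period within `harmonic_tol` (**0.01**) of the maximum
  wins.
- `N` never counts as a match, so assembly gaps cannot fake
  periodicity.

Arrays are found by sliding windows of 3 × `max_period` with 50%
overlap, merging adjacent windows that report the same period (±2 bp),
then refining boundaries outward and inward in period-sized steps
while the local score holds. Boundary resolution is therefore one
repeat unit; copy numbers are accurate to about ±1 copy, which is the
relevant precision for terminal classification. The consensus is the
per-column majority over phase-aligned full copies.

Terminal classification uses a `margin` of **0.1** of the scaffold
length: arrays within that margin of an end are terminal (nearer end
wins when both qualify, ties go left). Terminal arrays are the
orientation evidence consumed by `match_scaffolds`.

## Homology cutoffs (`tiled_identity`, `derive_cutoffs`)

Overall identity of a protein pair merges its alignment fragments into
one non-redundant tiling on the **query** axis: fragments are tiled
greedily in descending matched-count order and overlaps are truncated
against already-claimed columns (a truncated fragment keeps matches
pro-rata to its surviving columns). The greedy keep-the-stronger rule
is deterministic and order-independent; whether the identity
denominator should include subject-only gap columns is genuinely
ambiguous in common usage, and the query-column convention is chosen
and documented here. Best hits maximise identity, with ties broken by
tiled column count then subject id.

Cutoff derivation smooths an ingroup and an outgroup identity sample
with a Gaussian kernel (Silverman's rule bandwidth, 512-point grid on
[0, 1]); modes are interior local maxima at ≥ 10% of the global
maximum. The densities' crossing between their principal modes is the
natural boundary between "same-gene" and "background" homology: the
high cutoff is the crossing and the low cutoff is half of it,
reproducing the familiar 30/60% convention when the distributions
cross near 60%. Classification bins are half-open at the top
(`identity >= high` is high).

## Gene families

Tandem duplication follows the "less than 20 genes apart" rule read
literally: consecutive same-family members on a scaffold whose
gene-order indices differ by < `max_distance` (default **20**; exactly
20 is non-tandem). Whether "adjacent" should mean consecutive members
or any pair within the window is ambiguous; consecutive-members is the
default and `all_pairs = TRUE` gives the variant. Lineage-specific
clusters are clusters of size ≥ 2 whose members all come from one
species. Copy-number enrichment uses Fisher's exact test on the 2×2
family-vs-rest table with Benjamini–Hochberg adjustment across
families; the test choice is this package's, since figure-level
comparisons of this kind rarely name one, and it is reported as such.

## Translation efficiency (tAI)

Absolute adaptiveness of codon c is W(c) = Σⱼ (1 − s₍cj₎)·tGCNⱼ over
anticodons j that recognise c under the wobble rules; relative
adaptiveness w = W/max W, with W = 0 codons given the geometric mean
of the nonzero w (they can still be translated, just poorly); gene tAI
is the geometric mean of its codons' w, excluding the terminal stop
(initiator exclusion is a flag, default off). The selective
constraints default to the standard tAI parameterisation — wobble
G:U 0.41, I:C 0.28, I:A 0.9999, U:G 0.68, lysidine 0.89,
Watson–Crick 0 — and are fully overridable, since published analyses
typically delegate to these defaults without printing them.

Family comparisons use the Wilcoxon rank-sum test: exact by full
enumeration of rank assignments for combined n ≤ 20 (valid under
ties), normal approximation with continuity and tie correction above.
The test is two-sided with an explicit direction; a one-sided claim
("higher translation rates") is recovered as direction plus halved p,
which avoids silently encoding sidedness. One quirk inherited from the
literature this mirrors: a significance statement printed there as
"p ≥ 0.05" is treated as the evident typo for p ≤ 0.05; this package
flags families at adjusted p < 0.05 and reports both raw and adjusted
values.

## The synthetic-data generator

`simulate_genome()` emulates, with exported ground truth: a 24-block
ancestral order (30–60 genes per block) rearranged into an n = 7
signed karyotype; fragmentation into `n_scaffolds` (default 40)
scaffolds, flipped independently with probability 0.5 to exercise
orientation logic symmetrically; N-gap runs in 10% of intergenic
spacers; 177-bp satellite arrays of 30–60 copies planted at the
centromere-facing termini of pericentromeric scaffolds, with unit AT
fraction 0.7 and 1% per-copy per-base mutation so arrays are
detectable but not literal repeats; a two-component truncated-normal
identity mixture with modes 0.85/0.35 (sd 0.05/0.10, weight 0.6); and
codon-biased vs uniform gene sets under a deterministic tRNA pool.
Breakpoints fall between genes, at least six genes apart, and one
breakpoint is forced at the centromere whenever a chromosome receives
several scaffolds — this is what creates satellite-bearing centromeric
scaffold ends, mirroring assemblies that break at core centromeres.
The pericentromere's extent relative to the arms is not a settled
quantity, so it is a knob (`pericentromere_fraction`, default 0.05 of
the chromosome length) rather than a constant. Gene and intergenic
lengths (300/200 bp) are compressed relative to real genomes purely to
keep simulated genomes sub-megabase; none of the tested logic depends
on absolute scale.

What the generator deliberately does **not** model: sequence evolution
(identities are drawn, not evolved), repeat families other than the
planted satellite, segmental duplication, assembly chimerism, and
mapping ambiguity beyond uniform random mislabelling
(`mislabel_rate`). Passing recovery tests therefore shows the
algorithms are correct under clean and mildly noisy conditions, not
that they are robust to every artefact of a real assembly — real
paintings need the `min_run`/`max_interleave`/`|tau|` gates precisely
because real noise is structured.

## Numerical conventions

- Percentages printed in tables use round-half-even at the stated
  decimals (2 for non-gap and discrepancy percentages, 1 for gap
  fraction), so table cells are reproducible.
- N50/L50: N50 is the minimal scaffold count reaching half the span;
  L50 is the scaffold length at that point. Usage in the wild is
  inconsistent (sometimes reversed); this package fixes the convention
  that makes a printed "8/13.4 Mb" pair self-consistent.
- Contigs split at N runs of ≥ `min_gap_run` (default **10**, a common
  assembler convention); shorter N runs stay inside their contig.
- Ties: best-hit ties break by columns then lexicographic subject id;
  terminal-classification ties go left; the smallest period wins among
  near-equal autocorrelation scores.
- Determinism: every generator routine seeds the RNG from
  `config$seed` (plus a fixed per-stage offset), so a fixed config is
  byte-identical across runs, including FASTA/TSV/JSON output and SVG
  rendering.

## Problem sizes used in the tests

The shipped test-suite and acceptance script run entirely on simulated
data sized for thoroughness per unit time: 20-seed recovery batches
with 30–60 scaffolds per genome for karyotype assembly (~900 scaffold
placements per batch), 40 planted arrays for satellite recovery,
10,000-pair identity mixtures for mode/crossing recovery, 1,000 random
vectors against the N50 oracle, 100 random catalogs against the
brute-force tandem oracle, and full rank-enumeration Wilcoxon checks
up to combined n = 10. These sizes were chosen as the smallest that
make the stochastic recovery criteria stable across seeds.

## Known limitations

- The satellite finder assumes high-identity tandem arrays; diverged
  or higher-order-repeat satellites (dimeric units, strand switches)
  will be reported at the higher-order period or missed below the
  match threshold.
- `match_scaffolds` requires exact block-label runs; a scaffold whose
  painting contains a genuinely rearranged (non-contiguous) block
  order places only its longest matching run and reports the rest as
  conflicts, by design.
- Genome-wide satellite copy totals from a real assembly depend on how
  much pericentromeric sequence was assembled at all; synthetic
  recovery says nothing about that censoring.
- The enrichment and rank-sum tests assume independent genes; tandem
  arrays violate independence in exactly the families where they
  matter most, so flagged enrichments are screening results, not
  confirmatory statistics.
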