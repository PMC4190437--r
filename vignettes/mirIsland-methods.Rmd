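---
title: "Methods: coverage-island miRNA discovery and NB differential expression"
author: "mirIsland"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage-island miRNA discovery and NB differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirIsland)
```

# Scope and data model

mirIsland implements a desk-scale, fully testable version of a classic
small-RNA miRNome workflow: aligned reads are filtered, stacked into
genomic coverage islands, validated as hairpin precursors by secondary
structure prediction, classified as known or novel miRNAs, and tested
for differential expression between condition groups with a
negative-binomial exact test. The package keeps the Bioconductor data
model throughout: reads, islands and annotations are `GRanges`, genomes
are `DNAStringSet`s, the locus-by-library count matrix is a
`SummarizedExperiment`, and the simulation and analysis containers are
S4 classes with validity checks.

Because real miRNome studies hinge on genome-scale inputs, the package
ships a synthetic-data generator as a first-class module. Its output is
not a toy fixture: planted precursors, decoys, library design, true
counts and size factors constitute a complete ground truth against
which every downstream stage is validated in the test suite.

# Read-level filters

**Adaptor trimming** (`trimReads`). The 3' adaptor is searched at every
start position of each read; partial matches overhanging the 3' end are
allowed. A position qualifies when the overlap is at least `minOverlap`
(default 3) nt and the mismatch count is at most
`min(maxMismatch, overlap %/% 3)` with `maxMismatch = 2`. The scaled
budget matters: with a flat two-mismatch allowance every 1–2 nt tail
overlap would "match" and adaptor-free reads would always lose their
last bases, contradicting the requirement that untrimmed in-range reads
pass unchanged. After trimming, inserts outside 17–26 nt are discarded.
Trimming operates in nucleotide space; platform-specific color-space
encodings are out of scope, and the adaptor sequence is a parameter.

**Multimapper removal** (`filterMultimappers`). Reads whose total
alignment count (SAM `NH` tag) exceeds 6 are removed entirely. The
boundary is deliberately "remove only > 6": of the two plausible
readings (retain < 6 vs remove > 6) the removal rule is the explicit
one, so a read with exactly six alignments is kept. Retained
multimapped reads contribute a single counting placement — the first in
the aligner's best-to-worst order — to avoid double counting.

**ncRNA exclusion** (`removeNcrnaOverlaps`). A read is discarded when it
overlaps any annotated non-miRNA ncRNA interval by at least one base on
the same chromosome; miRNA-class annotations never trigger removal. The
overlap is strand-blind by default (the behaviour of interval
intersection tools commonly used for this step); a `sameStrand` flag is
available because the convention is genuinely ambiguous.

# Loci detection and quantification

Coverage is computed per base, pooled over libraries and strands
(`computeCoverage`), and islands are maximal runs of depth ≥ 1
(`detectIslands`). The retention rule "genomic coverage greater than 2"
is interpreted as *peak* depth > 2 rather than mean depth: miRNA loci
are read stacks, and a stack's evidence is its height. Both the
threshold and the interpretation are configurable through `minPeak`.
Islands are detected on pooled libraries so that all samples share one
row space; per-sample detection followed by merging would need a merge
rule that the underlying workflow leaves unspecified.

Counting (`countReads`) assigns a read to an island when at least 50%
of its bases fall inside (`minOverlapFrac`), each read at most once
(largest overlap wins). Since islands are built from the same reads,
retained reads normally lie fully inside their island; the fractional
rule exists for counting against externally supplied island sets. Each
island also records its modal read length — the downstream proxy for
the mature miRNA length — and the majority strand of its reads, which
orients precursor excision.

# Hairpin validation

For every island two candidate precursor windows are excised
(`exciseWindows`): `[start − 10, end + 50)` and `[start − 50, end + 10)`
in 0-based half-open coordinates, anchored on the island boundaries.
The two windows simulate the island being the 5p or the 3p arm of a
precursor whose other arm lies down- or upstream. Minus-strand islands
yield reverse-complemented sequences with the window roles swapped.
Both windows are folded and the lower-energy one is carried forward;
requiring both to pass would be stricter than the discovery contract
warrants, and which convention the original workflow used is not
recorded.

## The energy model

`foldMfe` minimizes, by an exact O(n³) dynamic program (implemented in
C++), the following energy over all pseudoknot-free structures with
pairs AU/UA/GC/CG/GU/UG and hairpin loops of ≥ 3 nt:

* a **stacking energy** for each pair immediately enclosing another,
  indexed by the strength classes of the two pairs
  (GC = −3.3, GC:AU = −2.2, GC:GU = −1.5, AU = −1.1, AU:GU = −0.8,
  GU = −0.5 kcal/mol);
* a **hairpin-loop penalty** `7.0 + 1.078·ln(L/3)` kcal/mol for a loop
  of length L (logarithmic extrapolation of Jacobson–Stockmayer form);
* a flat **interior penalty** of 5.0 kcal/mol for each pair closing a
  bulge, internal loop or multiloop branch.

`structureEnergy` is the single authoritative definition of this score;
the DP is verified against exhaustive enumeration of all structures on
short sequences. Ties are broken deterministically toward structures
whose outermost pair starts 5'-most.

This is deliberately *not* a re-implementation of the Turner rules: the
model keeps the contract that matters for discovery — a stability
threshold on a hairpin — while remaining small enough to verify
exactly. The constants were calibrated once, at design time, so that
the conventional −20 kcal/mol cutoff behaves under this model the way
it behaves under full thermodynamic folders: designed precursor stems
(20+ mostly-complementary pairs) fold to −40 to −70 kcal/mol, while the
99th percentile of uniform-random ~80-nt windows sits near
−18 kcal/mol. The hairpin base of 7.0 and interior penalty of 5.0 are
at the high end of physically reported initiation energies, which
suppresses the incidental 2–3-pair helices that random flanking
sequence would otherwise contribute to an MFE structure. All constants
live in `EnergyParams` and are user-replaceable; anyone substituting
their own parameters should recalibrate the `mfeThreshold` of
`classifyNovel` accordingly.

`isHairpin` operationalizes "potential hairpin structure" as: exactly
one terminal loop (a single stem-loop, bulges and internal loops
allowed, no multiloops) and at least 15 base pairs. Both knobs are
arguments.

## Classification

Islands overlapping a known miRNA annotation (strand-blind, ≥ 1 bp,
nearest midpoint on ties) are labelled *known*. The remaining
candidates are *novel* when all of: modal read length within 17–29 nt;
at least 1000 reads in at least one library; folding energy strictly
below −20 kcal/mol; hairpin topology. Each sub-filter is reported as a
flag so that rejection causes are auditable. The size filter applies to
the modal read length (the mature proxy) rather than the island width,
since reads, not loci, carry the mature length information.
Cross-species conservation support is available via `alignPrecursor`
(Smith–Waterman, match +1, mismatch −2, affine gaps 5 + 2(L−1), bit
score `(λS − ln K)/ln 2` with λ = 1.28, K = 0.46 for this scoring
scheme, conserved when > 90); it is informational and not part of the
novel filter.

# Differential expression

**Normalization.** Median-of-ratios size factors: for library *j*, the
median over loci (positive in every library) of the count divided by
the locus geometric mean. This makes normalized library medians
self-consistent and is robust to a minority of differentially expressed
loci.

**Dispersion.** Gene-wise method of moments on normalized counts,
`α̂ = max(0, (v − m)/m²)` with *v* the within-group pooled variance,
then a hyperbolic trend `a₀ + a₁/m` fitted across loci, and the working
value `max(α̂, trend)`. The maximum rule is conservative sharing: with
three replicates per group the gene-wise estimate is noisy, and taking
the larger of the two values trades a little power for type-I safety.
This is a documented simplification of the local-regression schemes in
mature DE packages; the exact-test contract is unchanged.

**Exact test.** Conditioned on the two-group total K, each split
(a, K−a) is scored by the product of two NB laws for the replicate-group
sums, with mean `μ_g = q₀ S_g` (q₀ = K divided by the summed size
factors) and variance `μ_g + α q₀² Σ_{j∈g} s_j²` — the exact first two
moments of a sum of independent NB replicates. Modeling the sum with
the per-replicate dispersion unadjusted would inflate the null variance
roughly by the replicate count and collapse the type-I rate to ~10⁻³;
the moment-matched form keeps the test calibrated (observed raw
p < 0.05 fraction ≈ 0.03–0.04 at α = 0.1, 3 vs 3 — conservative, as
expected from discreteness and the maximum-sharing dispersion). With
α = 0 the law degenerates to a binomial split. The p-value is the
probability mass of splits no more likely than the observed one, and
the test is symmetric in the groups.

**Multiplicity.** BH step-up on raw p-values; loci with zero counts in
both groups get p = 1 and are excluded from the number of tests (a
simple independent-filtering choice — they carry no information and
would only dilute the adjustment). Reporting tiers at adjusted p
0.1/0.05/0.01 are conventional; the package emits both raw and adjusted
values so either can be binned.

**Ordination.** `runBCA` performs between-class analysis: counts are
normalized, transformed by log2(x + 1) (a variance-stabilizing choice
the package makes explicit, since the upstream convention is not
recorded), locus-centered, averaged within groups, weighted-centered,
and eigen-decomposed with group-size weights. At most g − 1 axes are
non-degenerate for g groups; with singleton groups BCA coincides with
plain PCA, which the tests verify.

# The synthetic-data generator

`simulateMirnaExperiment` emulates a multi-library small-RNA experiment
of the loaded/unloaded, healthy/affected explant type: the default
design is one tissue with five condition groups of three libraries each
(H, OC, H_L, H_UL, OC_L). What it models:

* **Genome**: uniform-random chromosomes (default one of 50 kb).
* **Precursors**: designed stem-loops — a GC-rich arm (GC 0.6, stem
  26–30 bp), a 6–8 nt loop, and the arm's exact reverse complement —
  planted on random strands, non-overlapping, clear of edges. Mature
  arms are the outer 21 nt of each stem arm. The geometry guarantees
  folding far below −20 kcal/mol and keeps the whole precursor inside
  the +50-nt excision window of its mature-arm island.
* **Counts**: per-locus base means log-uniform on 50–5000 reads,
  NB dispersions 0.05–0.3, true library size factors uniform on
  0.5–2, a configurable DE fraction (default 10%) with fold change 4
  applied in the affected conditions — values chosen to match what
  desk-scale small-RNA libraries of this design plausibly produce, and
  matching the regimes the validation criteria specify.
* **Reads**: each counted read comes from the locus's expressed arm
  (5p with probability 0.8) with ±1 nt 5'-end jitter, giving 20–22 nt
  reads inside the 18–24 nt band typical of mature miRNAs. A configured
  fraction (default 5%) is duplicated to 2–8 alignment positions with
  the true placement first, exercising the NH-based filter; background
  reads (default 2/kb/library, 18–24 nt) are scattered uniformly.
* **Decoys**: annotated non-miRNA ncRNA loci with moderate expression
  (exercising the annotation filter), and unannotated expressed decoys
  with *structure-free* sequence: placements are rejection-sampled
  until the surrounding region (including every possible excision
  window) folds at or above −20 kcal/mol under default parameters.
  Because the MFE of a sub-window can never undercut the MFE of its
  enclosing region, this makes "decoy" a guaranteed negative control
  rather than a probabilistic one — uniform-random sequence alone forms
  a genuine sub-−20 hairpin in roughly 0.6% of 80-nt windows, which
  would otherwise contaminate the ground truth.
* **Low-abundance controls**: a configurable number of precursors whose
  counts are capped (default 999 per library) to probe the ≥ 1000
  abundance filter from below.

All randomness flows from one master seed through fixed stage offsets;
a fixed configuration reproduces byte-identical SAM output. What the
generator does **not** model: pooling of individuals within a library
(per-library means only), sequencing errors, adapter chimeras,
color-space artifacts, GC or ligation bias, and genome repeat
structure. Passing the end-to-end tests therefore demonstrates the
pipeline's correctness against its own contracts, not performance on
real libraries.

# Numerical and degenerate-input choices

* Folding requires ≥ 10 nt and A/C/G/U/T; T and U are interchangeable.
  The empty structure is always admissible, so MFE ≤ 0.
* Traceback ties prefer stacking over hairpin closure over interior
  decomposition, and 5'-most outermost pairs, with a 10⁻⁷ kcal/mol
  comparison tolerance.
* The exact test clamps p to [0, 1] and returns 1 when K = 0; pmf
  comparisons use a 1 + 10⁻⁸ relative guard so that ties in the split
  distribution are counted into the tail.
* Size factors are undefined (error, suggesting a pseudo-count) when no
  locus is positive in all libraries.
* Window excision clamps at chromosome bounds; islands on unannotated
  strands are treated as plus-strand.
* Dispersion trend fitting falls back to the median of positive
  gene-wise estimates when the regression is degenerate; negative
  fitted coefficients are floored at zero.

# Validation scale

The test suite validates the folding DP against exhaustive structure
enumeration (200 sequences of 12–14 nt), the exact test against
brute-force enumeration (100 cases, K ≤ 50, 10⁻⁹), BH against the
step-up definition (1000 vectors), size-factor recovery (2000 loci,
within 5%), type-I and power characteristics (2000 loci, 3 vs 3,
dispersion 0.1, ten replicate seeds), the full discovery pipeline
(30 planted precursors, 30 decoys, ~1.4 M reads) and BCA against an
explicit matrix oracle. These sizes keep the default run to about a
minute while leaving the statistical checks well-powered; the same
computations, re-run from scratch, are exported by
`scripts/acceptance.R`.

# Known limitations

* The energy model is a calibrated simplification; absolute MFE values
  are not comparable to thermodynamic folders, only the threshold
  behaviour is.
* Islands are strand-pooled and detected on pooled libraries; loci
  expressed antisense to each other merge.
* The dispersion trend is hyperbolic with two parameters, not a local
  regression; very low-count loci lean on the trend value.
* `annotateKnown` assigns one name per island (nearest midpoint);
  overlapping miRNA clusters are not disambiguated.
* The conditional exact test assumes the working dispersion is known;
  uncertainty in the dispersion estimate is not propagated.
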