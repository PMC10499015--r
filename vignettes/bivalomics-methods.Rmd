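---
title: "Promoter bivalency analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter bivalency analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bivalomics)
```

This vignette is the package's own account of the methods it implements:
the promoter-state model and its assumptions, the tunable parameters, what
the synthetic-data generator does and does not emulate, the numerical
conventions, and the design decisions that were genuinely open.

## The promoter-state model

A gene promoter is summarized by the joint occupancy of two histone marks
in a fixed window around the transcription start site: H3K4me3 (activating,
promoter-localized) and H3K27me3 (repressive, Polycomb-deposited). The
window is the TSS ± `flank` bases; `flank` defaults to 500 bp, and because
the window is symmetric about the TSS base it is strand-independent. In the
0-based half-open convention used throughout, the window is
`[max(0, tss - flank), tss + flank + 1)`, a 1001-base interval away from the
chromosome edge. Peak semantics are deliberately binary — a peak either
overlaps a region by at least one base or it does not; there is no
fractional-overlap option, and no signal-level thresholding at this stage.

Five mutually exclusive states partition the genes at each timepoint:

* `K4_ONLY` — at least one H3K4me3 peak overlaps the window, no H3K27me3;
* `K27_ONLY` — the mirror case;
* `BIVALENT` — peaks of both marks overlap the window **and** at least one
  H3K4me3/H3K27me3 peak pair overlaps each other by ≥ 1 bp;
* `DUAL_NONOVERLAP` — both marks hit the window but no pair of peaks
  overlaps;
* `NONE` — neither mark present.

The `DUAL_NONOVERLAP` state exists because the strict definition of
bivalency ("overlapping peaks at the TSS") does not cover promoters where
the two marks flank the TSS without touching; empirically the two marks'
peaks at bivalent regions do not always coincide. The `dual_policy`
parameter decides whether this configuration is kept separate (default,
the strict reading) or folded into `BIVALENT`. Folding can only grow the
bivalent class; every other class is unchanged. A related ambiguity — must
the K4∩K27 intersection itself overlap the window, or only each peak? — is
resolved as "each peak overlaps the window, and the peaks overlap each
other", the weaker and more inclusive reading.

One TSS per gene is assumed. Callers with isoform-level annotations must
collapse to a canonical TSS upstream; this keeps the state table a
partition over genes.

## Consensus peaks

Replicate peak calls are collapsed at base resolution: each replicate
contributes 0/1 coverage per base (after merging its own overlapping
peaks), and maximal runs of bases supported by at least `min_support`
replicates become consensus intervals. The default `min_support` is the
strict majority `floor(n/2) + 1`, which for two replicates demands both —
"majority" is not defined for even n by the usual phrase, and the strict
reading is the conservative one. Base-level voting (rather than whole-peak
reciprocal-overlap voting) was chosen because it is robust to boundary
jitter and has an exact, independently checkable per-base counting oracle;
with `min_support = 1` it reduces to the union and with `min_support = n`
to the intersection, which the tests assert.

## State dynamics

Transitions between timepoints are plain contingency tables of per-gene
state pairs; row sums equal the origin-state counts, and composing per-gene
assignments across intermediate timepoints reproduces the long-range table
exactly (no Markov assumption is made about the *data* — the table is a
deterministic function of the state table). Trajectory ("alluvial") tables
flag, but never drop, trajectories covering less than 0.5% of included
genes: the threshold exists purely for plot legibility, so it must not
change any downstream statistic. By default trajectory tables include only
genes that are bivalent or H3K27me3-only at some timepoint, the gene set of
interest for repressive-mark dynamics.

## Broad H3K4me3 domains

Peaks separated by a gap strictly below 1 kb are merged transitively, then
ranked by width in descending order, and the rank–width curve is split at
its elbow: the rank maximizing the perpendicular distance to the chord
joining the first and last point. This is the standard geometric knee
detector; it is deterministic, and its argmax is invariant to uniform
rescaling of either axis (the distance numerator is bilinear, the chord
length constant across ranks), so results do not depend on units. Ties are
broken toward the smallest rank.

One convention required a decision: whether the elbow rank itself is broad
or typical. For the width curve the elbow is treated as the *first typical
peak* (broad = ranks strictly before the elbow); on curves with an abrupt
width cliff the maximal-distance point is the first point after the cliff,
so this convention recovers exactly the planted broad set in simulation.
The degenerate case — a perfectly straight curve, e.g. all widths equal —
has zero distance everywhere; the tie rule then returns rank 1 and the
single widest peak is called broad, a documented convention that keeps the
broad/typical split a partition.

## Signal, normalization and the bivalency ratio

Mark signal at a promoter is the sum of per-base coverage over the TSS
window, taken from bedGraph tracks (overlapping bedGraph intervals are an
error — per-base coverage would be ambiguous). Samples are normalized by
median-of-ratios size factors: for each sample, the median over genes of
the ratio of its count to the gene's geometric mean across samples,
restricted to genes with all-positive counts. The bivalency ratio is then

```
ratio_g = log2((mean normalized K4_g + c) / (mean normalized K27_g + c))
```

with pseudocount `c = 1`. Both marks are normalized jointly (one combined
matrix), which makes the ratio exactly antisymmetric under swapping the
marks. This is an explicit, simple stand-in for a negative-binomial
pairwise contrast: no dispersion estimation and no shrinkage are applied,
so extreme ratios at low counts are damped only by the pseudocount. The
package consumes differential-expression tables as input rather than
re-deriving them; only normalization and the ratio are computed internally.

## Rank tests, Fisher tests, FDR

Expression differences across states use the Kruskal–Wallis rank test
followed by Dunn's post hoc z-tests (pooled ranks, tie-corrected variance),
with Benjamini–Hochberg adjustment across pairs. Dunn's test is implemented
directly from its textbook form since no installed package provides it; the
z statistic reduces to the classic untied formula, which a test asserts.

Proportion comparisons use Fisher's exact test. The two-sided p-value is
the sum of hypergeometric probabilities, over tables with the observed
margins, not exceeding the observed table's probability (with a `1 + 1e-7`
relative tolerance for floating-point ties, the same rule base R uses); the
odds ratio is the conditional maximum-likelihood estimate, with 0/Inf at
the support boundary. The implementation is written directly from this
definition — it is a one-screen function, and the exhaustive sweep over all
2×2 tables with total ≤ 60 then has an independent enumeration oracle to
compare against, with `stats::fisher.test` as a second cross-check on
random tables. BH adjustment delegates to `stats::p.adjust`.

Threshold boundary semantics follow the stated rules exactly and the tests
pin them: DE requires |log2FC| **≥** 1 and adjusted p **<** 0.01; TRAP
depletion requires TRAP/input **<** 0.6 in at least 3 of 4 timepoints
(with 0/0 treated as ratio 1 and x/0 as +∞); the bivalent-TF catalog
requires mean TPM **>** 5. Direction concordance between two DE tables
counts sign agreement among the first table's significant genes, without
requiring significance in the second table (a flag enables the stricter
reading).

## Cell-type markers

Metacell profiles (genes × cell types) are z-scored per gene with the
sample (n − 1) standard deviation — material at ~10 cell types — and
zero-variance rows are flagged and zeroed. A gene is a candidate marker of
the cell type where its z is maximal (making marker lists disjoint by
construction), provided that z is positive and at least 1.5× the gene's
second-highest z. The ratio rule applies only when the second z is
positive: ratios of negative z-scores are meaningless, and a gene whose
signal is confined to one type should pass. Surviving candidates are sorted
by z and cut at the elbow of the sorted curve, inclusive of the elbow rank.

Two design choices here deserve justification because the order of the two
rules is genuinely open:

* **Ratio rule before elbow.** If the elbow is computed on all argmax
  candidates, the long tail of background genes dominates the curve's
  geometry and drags the knee tens of ranks past the marker cliff — and the
  background genes it admits are precisely one-high-value rows whose second
  z is ≤ 0, which the ratio rule cannot reject afterwards. Applying the
  ratio rule first removes the bulk of the background from the curve, after
  which the knee lands on the marker corner. Both rules remain conjunctive:
  a marker must pass both.
* **Inclusive elbow.** On marker-like curves (a high plateau meeting a
  shallow tail at a corner) the maximal-distance point *is* the corner —
  the last marker — so the cutoff retains ranks up to and including the
  elbow. This differs from the width-curve convention above, where a
  discontinuous cliff puts the maximal-distance point on the first typical
  peak; each convention matches where the knee lands on its curve type.

Marker–bivalency enrichment is a per-cell-type 2×2 Fisher test of
(bivalent vs not) × (marker vs rest of genome), BH-adjusted across types.

## The synthetic-data generator

`simulate_bivalency_data()` builds a complete internally consistent dataset
from one seed: genes laid out every 20 kb across 4 chromosomes (so a peak
can never straddle two promoters), per-gene states drawn from priors at the
first timepoint and evolved through per-step transition matrices, peaks
centered on the TSS with state-appropriate marks (bivalent promoters get
mutually overlapping K4/K27 peaks), per-replicate boundary jitter
(Gaussian, default sd 50 bp) and dropout (default 5%), rectangular coverage
tracks, Poisson signal matrices, state-coupled lognormal TPM, DE tables
with planted signs, a metacell matrix with planted markers and TRAP/input
tables with a planted depleted subset. The defaults describe the study
design the package targets: three stages (P7, P12, P21), priors
(0.40, 0.25, 0.15, 0.20) over (K4-only, bivalent, K27-only, none) so
bivalency is highest in progenitors, and transition matrices chosen so that
roughly half of initially bivalent promoters resolve to K4-only by the last
stage (~51–53% lose H3K27me3 overall, with resolution accelerating in the
second step) while the K27-only class is stable (per-step maintenance
0.794, hence ~63% maintained across both steps). These are the dynamics the
method is meant to quantify, at magnitudes typical of committed neural
progenitor populations.

Choices worth flagging:

* **Quota transition sampling.** By default, destination states are
  allocated by largest-remainder quotas and assigned to random genes, so
  the planted matrix is the *exact* empirical transition table (up to
  rounding < 1/n per row). A truth manifest should be exact: recovery
  checks then measure pipeline error, not multinomial sampling error.
  `sampler = "multinomial"` provides the stochastic alternative, and a test
  verifies recovery within binomial error under it.
* **Ratio–expression link.** Bivalent genes carry a planted log2 balance
  `r ~ N(0, 2)`; their K4/K27 signals are `S0·2^(±r/2)` and their TPM is
  scaled by `2^(0.8 r)` with lognormal noise (sdlog 0.4). The link strength
  represents the strong observed correlation between the bivalency ratio
  and expression; with these defaults the recovered Spearman correlation is
  ≈ 0.93 at 1000 bivalent genes.
* **Bounded metacell noise.** Background metacell entries use uniform
  multiplicative noise on [0.6, 1.4] rather than a heavy-tailed law.
  Metacell profiles are pseudo-bulk averages over many cells, which damps
  outliers; more importantly, heavy-tailed per-type noise plants accidental
  single-type outlier genes that are *mathematically indistinguishable*
  from true markers — the z ceiling at 10 cell types is
  (n−1)/√n ≈ 2.85, which such outliers approach — making planted-marker
  recovery ill-posed for any caller. Bounded noise keeps the background
  z-range separated from the marker plateau.
* **Null mode.** `simulate_null_data()` keeps all shapes but permutes the
  state/expression coupling, draws DE status independently of state and
  places markers uniformly with no fold change. The calibration suite runs
  500 null replicates and checks that the Kruskal–Wallis omnibus, the
  pairwise DE-by-state Fisher family (any BH-adjusted rejection; under the
  global null this family-level rate equals the nominal level by Simes'
  identity) and the marker-enrichment family all reject at 5% within
  binomial error. The null replicates use large per-state counts
  (~2000 genes/state, DE rates 0.15) because exact conditional tests are
  conservative at small counts and their p-value distribution approaches
  uniformity only when the margins are sizable.

What the generator does **not** emulate: read-level data (no FASTQ/BAM),
fragment-length and GC effects, signal shape within peaks (coverage is
rectangular), enhancer bivalency, isoform structure, correlated replicate
noise, and compositional artifacts of real metacell normalization. Passing
the recovery suite therefore demonstrates that the pipeline's logic is
correct under the stated noise model — not that the thresholds would be
optimal on any particular real dataset.

## Numerical conventions and degenerate inputs

* All coordinates are 0-based, half-open (BED); conversion to 1-based
  closed happens only at the GenomicRanges boundary. No operation ever
  emits an interval with `start >= end` (property-tested).
* Chromosome name dialects are not normalized; names must match across
  inputs.
* Merging with `max_gap` is strict (`gap < max_gap`); the plain union also
  fuses bookended intervals, matching per-base semantics.
* Expression quintiles split by rank into sizes differing by ≤ 1 (extras to
  the lowest quintiles), ties broken by stable input order.
* `highest_stage` breaks ties toward the earliest stage and flags them.
* Empty peak sets, empty marker lists, states with zero genes and
  zero-variance metacell rows all degrade to warnings or NA rows, never
  errors; genuinely contradictory inputs (mixed marks in a consensus set,
  mismatched gene sets, overlapping bedGraph intervals) are errors.
* Pipeline runs are single-process and deterministic; the run manifest
  records parameters, seed, package version and per-file MD5 checksums,
  and a rerun on identical inputs is byte-identical.

## Problem sizes used by the test suite

The recovery checks run at 5000 genes × 3 timepoints (state, transition
recovery), 2050 peaks with 50 planted broad domains, 3300 genes × 10 cell
types with 30 markers each, 1000 bivalent genes for the ratio–expression
correlation, and 500 null replicates of 8000 genes for calibration — sizes
chosen so that each planted effect is estimated with sampling error well
inside its acceptance margin while the whole suite stays fast on one CPU.

## Known limitations

* State calls are peak-based; a promoter with sub-threshold signal in the
  peak caller is `NONE` here regardless of coverage, and no signal-level
  rescue is attempted.
* The bivalency ratio does not model count dispersion; at very low counts
  it is pseudocount-dominated.
* The region annotator (promoter > gene body > intergenic by midpoint) is
  a simplification of transcript-model-aware annotators and will differ
  near boundaries.
* The elbow cutoffs are geometric conventions; on curves without a real
  knee (near-linear width distributions) the broad/typical split is not
  meaningful, and the degenerate tie rule exists only to keep the output
  well-defined.
* "Majority of replicates" at n = 2 means both replicates; with many
  low-quality replicates base-level majority can be stricter than
  whole-peak voting.
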