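# bivalomics

Bivalent promoters carry both the activating histone mark H3K4me3 and the
Polycomb-deposited repressive mark H3K27me3, a configuration thought to
poise genes for later activation or silencing during differentiation.
`bivalomics` is an R toolkit for studying this phenomenon in developmental
ChIP-seq designs — for example proliferating neuronal progenitors profiled
at successive postnatal stages — where the questions are: which promoters
are bivalent, how does that change over development, which genes sit under
unusually broad H3K4me3 domains, and how does promoter state relate to
expression and to differential-expression outcomes.

It is aimed at genomics analysts who already have peak calls (BED or
narrowPeak), coverage tracks (bedGraph) and expression/DE tables, and want
a tested, reproducible implementation of the downstream state-calling and
enrichment analysis, plus a synthetic-data generator with planted ground
truth so every stage can be verified end to end without any external data.

## What it computes

* **Consensus peaks** per mark × timepoint: base-resolution majority
  voting across replicates; a base is retained when at least
  `floor(n/2) + 1` replicates cover it.
* **Promoter states**: each gene's TSS ± 500 bp window is classified as
  `K4_ONLY`, `BIVALENT` (a H3K4me3 peak and a H3K27me3 peak each overlap
  the window and overlap each other), `K27_ONLY`, `DUAL_NONOVERLAP`
  (both marks present but peaks disjoint) or `NONE`.
* **State dynamics**: transition matrices between timepoints, resolution
  fractions (e.g. the share of bivalent promoters that lose H3K27me3 by
  the final stage) and alluvial-style trajectory tables.
* **Broad H3K4me3 domains**: peaks closer than 1 kb are merged, ranked by
  width, and split into broad vs typical at the elbow (maximum
  perpendicular distance to the rank–width chord).
* **Bivalency ratio**: per gene,
  `log2((K4 + 1) / (K27 + 1))` on mark signals jointly normalized by
  median-of-ratios size factors — positive means H3K4me3-dominated.
* **Expression and DE integration**: per-state expression summaries with
  Kruskal–Wallis and Dunn's post hoc tests; DE filtering at
  |log2FC| ≥ 1 and adjusted p < 0.01; up/down composition per state
  compared with pairwise Fisher's exact tests under BH-FDR correction;
  direction concordance between two DE tables; the TRAP depletion filter
  (TRAP/input < 0.6 in ≥ 3 of 4 timepoints); a bivalent-TF catalog
  (bivalent at ≥ 1 stage, mean TPM > 5).
* **Cell-type markers**: z-scored metacell profiles, the 1.5× top-to-second
  rule plus an elbow cutoff, and per-type marker bivalency enrichment by
  Fisher's exact test.
* **Synthetic data**: `simulate_bivalency_data()` emits TSS tables,
  replicate peak calls with boundary jitter and dropout, coverage tracks,
  state-coupled TPM tables, DE tables, a metacell matrix with planted
  markers and TRAP tables — all with a truth manifest, byte-identical for
  a given seed. `simulate_null_data()` removes every planted coupling for
  type-I-error calibration.

## Worked example

```r
library(bivalomics)

b <- simulate_bivalency_data(sim_config(seed = 7, n_genes = 500,
                                        n_cell_types = 5,
                                        markers_per_type = 10))
cons <- lapply(setNames(nm = names(b$peaks)), function(m)
  lapply(setNames(nm = names(b$peaks[[m]])), function(tp)
    consensus_peaks(lapply(b$peaks[[m]][[tp]], peak_set,
                           mark = m, timepoint = tp))))
states <- classify_all(b$tss, cons)
states
#> <state_table> 500 genes x 3 timepoints (flank 500 bp, dual policy 'separate')
#>
#>                    P7 P12 P21
#>   K4_ONLY         202 234 263
#>   BIVALENT        123  85  53
#>   K27_ONLY         75  71  65
#>   DUAL_NONOVERLAP   0   0   0
#>   NONE            100 110 119

resolution_summary(states, "P7", "P21", "BIVALENT")
#>             state count   fraction
#> 1         K4_ONLY    60 0.48780488
#> 2        BIVALENT    46 0.37398374
#> 3        K27_ONLY    11 0.08943089
#> 4 DUAL_NONOVERLAP     0 0.00000000
#> 5            NONE     6 0.04878049
```

The state table shows the classic developmental pattern the generator
plants: bivalency is highest in the progenitor stage (123/500 at P7) and
declines with maturation, and the resolution summary shows ~50% of
P7-bivalent promoters resolving to H3K4me3-only by P21 — i.e. H3K27me3 is
removed as the genes commit. A full pipeline run
(`run_pipeline(list(seed = 1, output_dir = "out", simulate = list(...)))`)
writes every stage's table plus a checksummed run manifest, and reruns are
byte-identical.

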