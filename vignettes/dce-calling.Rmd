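---
title: "Calling and comparing domains of co-ordinated expression"
author: "dcescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and comparing domains of co-ordinated expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcescan)
```

## The model

Genes that are physically close on a chromosome are often co-regulated:
their expression rises and falls together across individuals. `dcescan`
formalizes this as *domains of co-ordinated expression* (DCEs): runs of
consecutive fixed-width chromosomal bins whose expression profiles are
significantly inter-correlated across the samples of a group, delimited by
statistically validated boundaries. The calling strategy adapts the
sliding-window boundary logic used by topologically-associating-domain
callers on Hi-C contact maps, substituting a permutation-masked Spearman
correlation matrix of binned expression for the contact matrix.

The pipeline, per chromosome and per sample group:

1. **Preparation.** Gene-level raw counts are filtered (fourteen excluded
   biotypes, duplicate `gene_name` entries spanning several chromosomes),
   genes with all-zero counts are dropped, and the matrix is normalized by
   relative log expression (median-of-ratios) followed by gene-length
   normalization (per kilobase of annotated gene-body span).
2. **Binning.** Each chromosome is split into 10 kb bins anchored at the
   start of its first gene and ending at the end of its last gene; a bin's
   value per sample is the mean normalized expression of the genes it
   contains. A gene contributes to every bin its span overlaps.
3. **Robust correlation.** The Spearman correlation matrix over a group's
   surviving bins is computed, and every coefficient is tested by a
   Monte-Carlo permutation scheme: each sample's bin values are shuffled
   independently, the full matrix is rebuilt once per round, and the
   p-value is the plain fraction of rounds in which the permuted
   coefficient was as or more extreme (two-sided, on |rho|) than the
   observed one. Coefficients with p > 0.05 are set to zero.
4. **Bin signal.** Two juxtaposed w-bin windows slide along the chromosome;
   at each position the mean of the w x w cross-window block of masked
   correlations is assigned to the downstream-most bin of the upstream
   window. This collapses the matrix into a 1-D profile of local
   co-expression.
5. **Segmentation.** A cubic smoothing spline (smoothness chosen by
   generalized cross-validation) is fit to the signal; local minima of the
   smoothed profile with value below the signal threshold become candidate
   boundaries. Each boundary is validated by a one-sided rank-sum test
   comparing the pairwise correlations among the w domain bins adjacent to
   the boundary ("within") against the w x w cross block spanning it
   ("in-between"); failing boundaries are chopped one bin towards the
   domain centre and retested, and domains that never reach significance
   are discarded. Finally, neighbouring domains separated by at most two
   low-signal bins are fused, with at most two intervening low bins per
   fused chain (hence at most three domains per fusion).

Two segmentations are compared by the Jaccard index of overlapping domain
pairs, by the BP segmentation distance (both interval sets are completed
into partitions of the chromosome and overlapping segment pairs contribute
`o * (1 - o / max(|a|, |b|)) / N`), and by a seven-way dynamics
classification: *intact*, *depleted*, *emerged*, *split*, *merged*,
*expanded*, *contracted*. Genes stranded between the fragments of a split —
inside the reference domain, outside every query domain, intersecting the
inter-fragment gap — are *disruptors*. Enrichment of domain categories in
gene sets and interval tracks uses a randomized-placement null (domain
sizes preserved, placed uniformly and without overlap over the group's
eligible-bin territory within each chromosome). Enhancer-promoter links
are *nested* when both anchors fall inside one domain and *disrupted* when
a link nested in the reference is no longer nested in the query.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `binSize` | 10000 | bp | bin width; sets the resolution of all downstream coordinates |
| `w` | 3 | bins | window size of the bin signal and the boundary tests; selectable by `tuneWindow()` (maximizing mean intra-domain correlation on a designated chromosome/group, ties to the smallest w) |
| `threshold` | 0.25 | signal units | qualifying-minimum and fusion low-signal cutoff; the reference group's genome-average signal. `dceConfig()` takes any fixed value; recomputing a reference average and passing it in reproduces the "auto" behaviour |
| `maskAlpha` | 0.05 | — | permutation-mask significance level |
| `nPerm` | 1000 | rounds | permutation rounds per chromosome (validation protocols below use 200–500 to keep runs short; p-resolution is 1/nPerm) |
| `alpha` | 0.05 | — | boundary-test significance level |
| `minSize` | 2 | bins | smallest testable domain (a 1-bin domain has no within-pair) |
| `maxGapBins`, `maxLowBins`, `maxChain` | 2, 2, 3 | bins / domains | fusion limits |
| `intactJaccard` | 0.8 | — | one-to-one pairs at or above this Jaccard are intact |

## Design choices in detail

Several steps of the procedure are underdetermined by the verbal
description of the method; the package fixes them as follows.

**Candidate segments.** Candidate domains are the segments between
consecutive qualifying minima, *including* the flanking minimum bins, and a
segment qualifies when its smoothed signal rises above the threshold
anywhere inside. Both choices follow from the refinement step only ever
moving boundaries *inward*: candidates must start at or outside the true
domain edge, and with realistically wide low-signal gaps between domains a
mean-based qualification would reject genuine domains flanked by long
near-zero stretches. The spurious low-signal margin a candidate inherits
this way is exactly what the chopping loop removes.

**Boundary test.** The rank-sum test enumerates the exact null distribution
of the midrank statistic whenever `choose(n1 + n2, n1) <= 1e5` assignments
exist — which covers the boundary geometry at the default w (3 within vs 9
between values) — and otherwise uses the tie-corrected normal approximation
without continuity correction. The exact path matters: masked matrices are
full of tied zeros, and the normal approximation under such ties can be
anticonservative by a factor of five, freezing boundaries outside the true
edge. An all-tied input (e.g. a fully masked neighbourhood) carries no
evidence and returns p = 1, so refinement keeps walking. Boundaries at the
chromosome edge have no outside bins, are untestable, and pass with p = NA.

**Masked zeros.** Coefficients zeroed by the mask participate as 0 in both
the bin signal and the boundary tests, consistent with their
interpretation as "no detectable correlation".

**Edges and degenerate inputs.** The first and last w−1 positions have no
full window pair; they inherit the nearest admissible signal value and
cannot host minima. A constant smoothed signal yields no domains. Bins
that are empty, zero-mean or constant within the group are removed before
correlation (`survivingBins()`); domains are called on the surviving-bin
axis and may not bridge more than `maxGapBins` consecutive missing bins in
genomic space, which prevents spurious mega-domains across gene deserts.
Plateau minima take their leftmost position. If the spline fit fails
(degenerate input), the raw signal is used unsmoothed.

**Classification precedence.** Labels are decided per connected component
of the overlap graph: no partner → depleted/emerged; one-to-one → intact
(Jaccard at or above the cutoff, or equal lengths), else
expanded/contracted by which side is longer; components with several
domains on one side are split when the query side is the fragmented one
(its union fits inside the reference side expanded by one bin of
tolerance), merged in the mirror case, and otherwise resolved by piece
count, then total bp, then largest piece. All members of a component share
its label, so swapping reference and query exactly exchanges
depleted↔emerged, split↔merged, expanded↔contracted.

**Empirical p-values.** The correlation mask uses the plain fraction
k/nPerm (minimum attainable p is 0); the enrichment tests use
(k+1)/(n+1) with two-sided values reported as the doubled smaller tail
capped at 1. The asymmetry is deliberate: the mask's literal-fraction
definition is part of the masking rule, while enrichment p-values are
reported as evidence and should never be exactly zero.

**RLE scaling.** Median-of-ratios normalization removes per-sample library
size up to a single global factor: scaling one of S samples by c rescales
the whole normalized matrix by c^(1/S) (the geometric-mean reference
absorbs the rest). Sample-to-sample ratios, and therefore all downstream
rank correlations, are invariant. Gene length is the annotated gene-body
span by default (`length_mode = "exon_union"` is available when exon
features are supplied); length normalization is a per-gene rescaling and
cannot change Spearman correlations between bins with fixed gene content —
it matters only where bins mix genes.

**BP distance.** Implemented from its published definition (uncovered
regions become background segments; bookended domains stay distinct
segments), and cross-checked in the tests against an independent
per-basepair label-table implementation.

**Determinism.** One master seed; the chromosome stream is derived as
`(seed + 7919 * chrom_index) mod (2^31 - 1)` and the permutation rounds
consume it sequentially. Identical data and configuration reproduce every
output byte for byte (the run manifest of `runPipeline()` records all
parameters, seeds and file digests).

## The synthetic-data generator

`simulateAnnotation()` tiles chromosomes with non-overlapping 6 kb genes
(one per 10 kb bin by default); `simulateCounts()` draws negative-binomial
counts (dispersion 0.1, log-normal baseline means with median ≈ 50 counts
shared across groups) in which the genes of a planted block share a
per-sample latent factor: gene i in block k has mean
`mu_i * exp(lambda * g_ks + eps)`, with `g_ks ~ N(0,1)`,
`eps ~ N(0, 0.3)` and loading `lambda = 1` by default. Group differences
enter only through block geometry, never through library-size confounds,
so recovery failures indicate algorithmic problems rather than
normalization artefacts. `makeScenario()` scripts paired two-group block
layouts whose ideal segmentations realize each of the seven dynamics
categories (plus a stable anchor domain in both groups), and
`runScenario()` runs them end to end.

The generator emulates the statistical structure the domain model assumes
— blockwise latent co-expression on top of overdispersed counts — and
deliberately omits much of what real RNA-seq data contain: isoform
structure, GC and mappability bias, batch effects, correlated
cell-type-composition variation, irregular gene density and gene-length
distributions, and inter-block correlation. Passing the validation suite
therefore demonstrates that the implementation recovers the structure it
models under realistic noise, not that every domain called on real data is
biologically real.

## Validation protocol and problem sizes

The test suite and `scripts/acceptance.R` recompute, from scratch:

- *Planted-boundary recovery*: one chromosome of 500 bins, 10 planted
  blocks of 8–30 bins (≥ 5-bin gaps), lambda 1, 50 samples, 200 permutation
  rounds; fraction of the 20 planted boundaries recovered within ±1 bin.
- *Mask calibration*: 40 i.i.d. bins × 30 samples, 500 rounds, 10 seeds;
  retained off-diagonal fraction versus alpha = 0.05.
- *Null DCE rate*: structured counts shuffled within every sample
  (200 bins, 10 seeds); fraction of eligible bins covered by calls.
- *Oracle equivalence*: bin signal, Spearman, exact rank-sum, Jaccard and
  BP distance against independent brute-force implementations on 100
  random instances each.
- *Scenario accuracy*: the seven dynamics scenarios over replicate seeds
  (20 in the tests, 10 in the acceptance script), 150 bins, 50 samples per
  group, 200 rounds.
- *Fusion audit*: exhaustive enumeration of all domain/gap/signal
  configurations up to 5 domains with gaps ≤ 3 bins (≈ 41 000
  configurations) against an independent reading of the fusion criteria.
- *EP disruption*: 50 planted links in the split scenario; links spanning
  the planted split must be disrupted, links inside a surviving fragment
  must not.

These sizes are the package's validation protocol: large enough for the
asymptotic properties to show (a 1/nPerm p-resolution well below alpha,
block widths spanning the fusion and minimum-size regimes), small enough
to run routinely.

## Known limitations

- The bin signal mixes all genes in a bin; antagonistically regulated
  genes sharing a bin cancel rather than segment.
- The permutation mask tests each coefficient marginally; no multiplicity
  correction is applied across the matrix (by design — masking is a
  denoising step, not an inference).
- Boundary refinement only shrinks domains, so a candidate segment that
  starts strictly inside a true domain cannot grow back; the
  minima-with-margin candidate rule exists precisely to avoid that state.
- Comparisons are pairwise against one reference; no multi-group joint
  classification.
- Placement nulls treat eligible bins as exchangeable territory and ignore
  fine-scale covariates (gene density within bins, GC).
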