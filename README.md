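# dcescan

Detection and comparison of **Domains of Co-ordinated Expression (DCEs)**
from bulk RNA-seq counts.

Genes that sit near each other on a chromosome are often co-regulated, and
diseases with broad transcriptional deregulation can fragment or
redistribute that spatial co-expression. `dcescan` finds the domains in
which it is organized: gene-level counts are normalized (relative log
expression followed by gene-length correction), averaged into fixed 10 kb
chromosomal bins, and each group's bin-by-bin Spearman correlation matrix
is denoised by a Monte-Carlo permutation mask (coefficients whose |rho| is
not more extreme than in shuffled data at alpha = 0.05 are zeroed). Sliding
two juxtaposed w-bin windows converts the masked matrix into a 1-D *bin
signal* s(i) = mean of the w x w cross-window block at position i; domains
are the segments between sub-threshold local minima of a smoothing-spline
fit of s, with every boundary validated by a one-sided rank-sum test of
"within" versus "in-between" correlations (failing boundaries are chopped
inward one bin at a time), and neighbouring domains fused when separated by
at most two low-signal bins (at most three domains per fusion). It is the
expression-correlation analogue of a topological-domain caller on Hi-C
matrices.

On top of the caller, the package compares two segmentations — Jaccard
index of overlapping pairs, the size-aware BP segmentation distance, and a
seven-way dynamics classification (intact / depleted / emerged / split /
merged / expanded / contracted) — extracts *disruptor genes* stranded in
split loci, runs randomized-placement enrichment tests of domains against
gene sets and interval tracks (e.g. Hi-C subcompartments, ATAC peaks),
scores enhancer–promoter link disruption, and provides Shannon-entropy
utilities for cell-type-composition comparisons. A fully scripted
synthetic-data module (negative-binomial counts with planted
latent-factor co-expression blocks) makes every stage testable without
access to patient data.

Intended users: computational biologists analysing grouped bulk
transcriptomes (e.g. disease-activity strata versus healthy controls) who
want statistically validated co-expression domains and their group
dynamics.

## Worked example

Simulate a healthy group carrying one co-expression block (bins 21–61 of a
150-bin chromosome) and a patient group in which that block is split in
two, then call and compare domains:

```r
library(dcescan)

cfg   <- simConfig(nBins = 150, nSamples = 50)
genes <- simulateAnnotation(cfg)
healthy <- simulateCounts(genes, cfg, blockSpec("chr1", 21, 61),
                          seed = 1, samplePrefix = "h")
patient <- simulateCounts(genes, cfg,
                          rbind(blockSpec("chr1", 21, 35),
                                blockSpec("chr1", 46, 61)),
                          seed = 2, samplePrefix = "p")

prep   <- prepareExpression(cbind(healthy, patient), genes)
binned <- binExpression(prep$expr, prep$genes)
h <- callDCEs(binned, colnames(healthy), "healthy",
              dceConfig(nPerm = 200, seed = 3))
p <- callDCEs(binned, colnames(patient), "patient",
              dceConfig(nPerm = 200, seed = 4))
h
#> DCESet: healthy - 1 domains
#>   chromosomes: chr1
#>   span: median 410000 bp, total 410000 bp
p
#> DCESet: patient - 2 domains
#>   chromosomes: chr1
#>   span: median 155000 bp, total 310000 bp

rep <- classifyDCEs(h, p)
rep
#> DynamicsReport: 1 reference / 2 query DCEs
#>        label ref query all ratio
#> 4      split   1     2   3     1
#> (other categories 0)

head(disruptorTable(rep, h, p, prep$genes), 3)
#>          ref_dce                     fragments          gene
#> 1 healthy_chr1_1 patient_chr1_1,patient_chr1_2 g_chr1_0036_1
#> 2 healthy_chr1_1 patient_chr1_1,patient_chr1_2 g_chr1_0037_1
#> 3 healthy_chr1_1 patient_chr1_1,patient_chr1_2 g_chr1_0038_1

coverageStats(h, eligibleBins(binned, colnames(healthy)))$genomeFraction
#> [1] 0.2733333
```

The healthy caller recovers the planted 41-bin block as one 410 kb domain
(27.3% of the chromosome's expressed bins); the patient segmentation
fragments it, the comparison labels the event a *split*, and the disruptor
table lists exactly the genes of the planted inter-fragment gap
(bins 36–45). Real data enter through `readGeneAnnotation()` (GTF),
`readCounts()` / `readSampleMetadata()` (TSV; patients are stratified by
SLEDAI score: low ≤ 2, intermediate 3–8, high > 8), with BED/TSV writers
for every artefact and `runPipeline()` (or `inst/scripts/dcescan.R`) to
drive the staged workflow from a YAML config with a reproducible run
manifest.

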