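# Small in-code fixtures shared by the unit tests.

mkGenes <- function(names, chrom, starts, ends,
                    types = rep("protein_coding", length(names))) {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends),
                           gene_name = names, gene_type = types)
}

# Wrap a symmetric matrix as a MaskedCorrelation with all entries retained.
mkMasked <- function(m, chrom = "chr1", group = "g",
                     binIndexMap = seq_len(nrow(m))) {
    new("MaskedCorrelation", chrom = chrom, group = group,
        binIndex = as.integer(binIndexMap), rho = m,
        pval = matrix(0, nrow(m), ncol(m)), maskedRho = m,
        nPerm = 1L, alpha = 0.05, seed = 1L, sided = "two")
}

mkSignal <- function(values, w = 3L, binIndexMap = seq_along(values)) {
    new("BinSignal", chrom = "chr1", group = "g", w = as.integer(w),
        values = as.numeric(values), smoothed = as.numeric(values),
        binIndex = as.integer(binIndexMap))
}

# Block-diagonal "perfect domain" correlation matrix: blocks of rho inside,
# zero elsewhere, unit diagonal.
mkBlockMatrix <- function(n, blocks, rho = 0.8) {
    m <- matrix(0, n, n)
    for (b in blocks) m[b, b] <- rho
    diag(m) <- 1
    m
}

mkDceGR <- function(chrom, starts, ends, ids = NULL) {
    gr <- GenomicRanges::GRanges(rep(chrom, length(starts)),
                                 IRanges::IRanges(starts, ends))
    gr$dce_id <- if (!is.null(ids)) ids
                 else if (length(gr)) paste0("d", seq_len(length(gr)))
                 else character(0)
    gr
}

# A tiny deterministic BinnedExpression with a planted block, for caller
# smoke tests. Low dispersion keeps the block signal strong at small n.
mkScenarioBinned <- function(nBins = 60, nSamples = 20, blocks = NULL,
                             seed = 7, ...) {
    cfg <- simConfig(nBins = nBins, nSamples = nSamples, seed = seed, ...)
    genes <- simulateAnnotation(cfg)
    counts <- simulateCounts(genes, cfg, blocks, seed = seed + 1)
    prep <- prepareExpression(counts, genes)
    list(binned = binExpression(prep$expr, prep$genes, binSize = cfg$binSize),
         samples = colnames(counts), genes = prep$genes, cfg = cfg)
}
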