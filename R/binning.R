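#' Build the fixed-width bin grid for one chromosome
#'
#' Bins of \code{binSize} bp tile the chromosome starting at the start of the
#' first gene and ending at (or just past) the end of the last gene:
#' n_bins = ceiling(span / binSize), where span runs from the first gene's
#' start to the last gene's end. A gene ending exactly on a bin edge adds no
#' extra bin.
#'
#' @param genes annotation GRanges.
#' @param chrom chromosome to tile.
#' @param binSize bin width in bp (default 10 kb).
#' @return GRanges of bins (metadata column \code{bin_id}, 1-based), with
#'   \code{binSize} and \code{anchor} in \code{metadata()}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 35000),
#'         gene_name = "A", gene_type = "protein_coding")
#' buildBinGrid(gr, "chr1")  # 3 bins anchored at 5001
#' @export
buildBinGrid <- function(genes, chrom, binSize = 10000) {
    .assertScalarNumber(binSize, "binSize")
    g <- genes[as.character(seqnames(genes)) == chrom]
    if (length(g) == 0L) stop("no genes on chromosome ", chrom)
    anchor <- min(start(g))
    span <- max(end(g)) - anchor + 1
    nBins <- ceiling(span / binSize)
    starts <- anchor + (seq_len(nBins) - 1L) * binSize
    gr <- GRanges(chrom, IRanges(start = starts,
                                 end = starts + binSize - 1L),
                  bin_id = seq_len(nBins))
    metadata(gr) <- list(binSize = binSize, anchor = anchor, chrom = chrom)
    gr
}

#' Bin gene-level expression into chromosomal bins
#'
#' Each bin's value per sample is the arithmetic mean of the normalized
#' expression of the genes assigned to it. By default a gene contributes to
#' every bin its span overlaps by at least 1 bp (\code{assignment = "span"});
#' \code{assignment = "tss"} assigns a gene only to the bin of its
#' strand-aware 5' end. Bins with no genes hold NA; bin geometry and the
#' gene map are independent of the expression values.
#'
#' @param expr normalized matrix (genes x samples, rownames = gene names).
#' @param genes annotation GRanges covering the matrix genes.
#' @param grid optional precomputed bin grid GRanges (one chromosome); when
#'   NULL, grids are built per chromosome with [buildBinGrid()] and stacked.
#' @param binSize bin width used when \code{grid} is NULL.
#' @param assignment "span" (overlap, default) or "tss".
#' @return a [BinnedExpression-class].
#' @export
binExpression <- function(expr, genes, grid = NULL, binSize = 10000,
                          assignment = c("span", "tss")) {
    assignment <- match.arg(assignment)
    expr <- as.matrix(expr)
    genes <- genes[as.character(genes$gene_name) %in% rownames(expr)]
    if (length(genes) == 0L) stop("no annotated genes in the matrix")
    if (is.null(grid)) {
        chroms <- unique(as.character(seqnames(genes)))
        grid <- suppressWarnings(do.call(c, lapply(chroms, function(ch)
            buildBinGrid(genes, ch, binSize))))
    }
    anchors <- if (assignment == "tss") resize(genes, 1L, fix = "start")
               else genes
    ov <- findOverlaps(grid, anchors)
    gn <- as.character(genes$gene_name)[subjectHits(ov)]
    ridx <- match(gn, rownames(expr))
    bin <- queryHits(ov)

    vals <- matrix(NA_real_, nrow = length(grid), ncol = ncol(expr),
                   dimnames = list(NULL, colnames(expr)))
    if (length(bin)) {
        cnt <- tabulate(bin, nbins = length(grid))
        for (j in seq_len(ncol(expr))) {
            s <- rowsum(expr[ridx, j], bin)
            vals[as.integer(rownames(s)), j] <- s / cnt[cnt > 0]
        }
    }
    geneList <- CharacterList(split(gn, factor(bin, levels = seq_along(grid))))
    gridAnno <- grid
    mcols(gridAnno)$nGenes <- tabulate(bin, length(grid))
    mcols(gridAnno)$geneList <- geneList
    se <- SummarizedExperiment(assays = list(meanExpr = vals),
                               rowRanges = gridAnno)
    new("BinnedExpression", se)
}

#' Surviving (eligible) bins for a sample group
#'
#' A bin survives for a group when it contains genes, its mean expression
#' over the group's samples is positive, and it is not constant across the
#' group (zero variance carries no rank information). These bins form the
#' axis on which correlation matrices and DCEs are computed; their grid
#' indices convert DCE coordinates back to genomic bp.
#'
#' @param binned a [BinnedExpression-class].
#' @param samples sample ids (columns) of the group.
#' @param chrom optional chromosome restriction.
#' @return integer vector of surviving bin rows (positions in the grid).
#' @export
survivingBins <- function(binned, samples, chrom = NULL) {
    v <- assay(binned, "meanExpr")[, samples, drop = FALSE]
    keep <- rowSums(is.na(v)) == 0L & rowMeans(v) > 0 &
        apply(v, 1, function(x) max(x) > min(x))
    if (!is.null(chrom))
        keep <- keep & as.character(seqnames(rowRanges(binned))) == chrom
    which(keep)
}

#' Genomic ranges of a group's eligible bins
#'
#' @inheritParams survivingBins
#' @return GRanges of the surviving bins (used as placement territory by the
#'   enrichment tests and as denominator by [coverageStats()]).
#' @export
eligibleBins <- function(binned, samples, chrom = NULL) {
    rowRanges(binned)[survivingBins(binned, samples, chrom)]
}
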