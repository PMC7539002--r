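#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomeInfoDb
#' @import GenomicRanges
#' @import SummarizedExperiment
NULL

#' BinnedExpression: per-bin mean expression along chromosomes
#'
#' A thin extension of \linkS4class{RangedSummarizedExperiment} holding one
#' assay (\code{"meanExpr"}) of per-bin mean normalized expression, bins x
#' samples. \code{rowRanges} carries the fixed-width bin grid (one range per
#' bin, all chromosomes concatenated) with per-bin gene lists in
#' \code{rowData} (columns \code{nGenes} and \code{geneList}). Bins without
#' genes hold \code{NA} in the assay.
#'
#' @seealso [binExpression()], [buildBinGrid()]
#' @export
setClass("BinnedExpression", contains = "RangedSummarizedExperiment")

setValidity("BinnedExpression", function(object) {
    if (!"meanExpr" %in% assayNames(object))
        return("assay 'meanExpr' is required")
    if (!all(c("nGenes", "geneList") %in% colnames(rowData(object))))
        return("rowData must contain 'nGenes' and 'geneList'")
    v <- assay(object, "meanExpr")
    if (any(v[!is.na(v)] < 0))
        return("mean expression values must be non-negative")
    TRUE
})

#' MaskedCorrelation: permutation-thresholded Spearman matrix for one
#' chromosome and one sample group
#'
#' Holds the observed bin-by-bin Spearman matrix, the matrix of Monte-Carlo
#' permutation p-values, and the masked matrix in which coefficients with
#' p > alpha are set to 0. \code{binIndex} maps matrix rows back to bin rows
#' of the originating [BinnedExpression] (the "surviving bin" axis).
#'
#' @slot chrom chromosome name.
#' @slot group sample-group label.
#' @slot binIndex integer indices of surviving bins in the full bin grid.
#' @slot rho observed Spearman coefficients (symmetric, unit diagonal).
#' @slot pval permutation p-values (plain fraction k / nPerm; diagonal 0).
#' @slot maskedRho rho with entries at pval > alpha zeroed.
#' @slot nPerm,alpha,seed permutation-test parameters.
#' @slot sided "two" (extremeness on |rho|) or "one".
#'
#' @seealso [permutationMask()]
#' @export
setClass("MaskedCorrelation", representation(
    chrom = "character",
    group = "character",
    binIndex = "integer",
    rho = "matrix",
    pval = "matrix",
    maskedRho = "matrix",
    nPerm = "integer",
    alpha = "numeric",
    seed = "integer",
    sided = "character"
))

setValidity("MaskedCorrelation", function(object) {
    n <- nrow(object@rho)
    if (ncol(object@rho) != n) return("rho must be square")
    if (!all(dim(object@pval) == c(n, n)) ||
        !all(dim(object@maskedRho) == c(n, n)))
        return("pval and maskedRho must match rho dimensions")
    if (length(object@binIndex) != n)
        return("binIndex length must equal nrow(rho)")
    ok <- !is.na(object@rho)
    if (any(abs(object@rho[ok]) > 1 + 1e-8))
        return("|rho| must be <= 1")
    if (max(abs(object@rho - t(object@rho)), na.rm = TRUE) > 1e-8)
        return("rho must be symmetric")
    m <- object@maskedRho; r <- object@rho
    off <- ok & !is.na(m)
    if (any(m[off] != 0 & abs(m[off] - r[off]) > 1e-12))
        return("maskedRho entries must be 0 or equal rho")
    if (object@nPerm < 1L) return("nPerm must be >= 1")
    TRUE
})

#' BinSignal: the 1-D local co-expression signal along a chromosome
#'
#' \code{values} holds, for every surviving bin, the mean of the w x w
#' cross-window block of masked correlations around that position (edge
#' positions inherit the nearest admissible value); \code{smoothed} holds a
#' cubic smoothing-spline fit evaluated at the same positions.
#'
#' @seealso [binSignal()]
#' @export
setClass("BinSignal", representation(
    chrom = "character",
    group = "character",
    w = "integer",
    values = "numeric",
    smoothed = "numeric",
    binIndex = "integer"
))

setValidity("BinSignal", function(object) {
    if (length(object@values) != length(object@smoothed))
        return("values and smoothed must have equal length")
    if (length(object@binIndex) != length(object@values))
        return("binIndex must match values")
    if (any(!is.finite(object@values)))
        return("signal values must be finite")
    if (object@w < 1L) return("w must be >= 1")
    TRUE
})

#' DCESet: one group's segmentation into domains of co-ordinated expression
#'
#' @slot domains a sorted, non-overlapping \link[GenomicRanges]{GRanges} with
#'   metadata columns \code{dce_id}, \code{start_bin}, \code{end_bin}
#'   (inclusive indices on the surviving-bin axis), \code{mean_signal},
#'   \code{left_p}, \code{right_p} (NA for untestable chromosome-edge
#'   boundaries) and \code{genes} (a CharacterList).
#' @slot group sample-group label.
#' @slot params the full calling configuration (see [dceConfig()]).
#'
#' @seealso [callDCEs()]
#' @export
setClass("DCESet", representation(
    domains = "GRanges",
    group = "character",
    params = "list"
))

setValidity("DCESet", function(object) {
    gr <- object@domains
    need <- c("dce_id", "start_bin", "end_bin", "mean_signal",
              "left_p", "right_p")
    if (!all(need %in% colnames(mcols(gr))))
        return(paste("domains must carry columns:",
                     paste(need, collapse = ", ")))
    if (length(gr) > 1) {
        ov <- findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
        if (length(ov) > 0) return("domains must not overlap")
    }
    if (any(mcols(gr)$end_bin < mcols(gr)$start_bin, na.rm = TRUE))
        return("end_bin must be >= start_bin")
    TRUE
})

#' DynamicsReport: seven-way classification of two DCE segmentations
#'
#' Produced by [classifyDCEs()]. \code{refLabels} and \code{queryLabels} are
#' data.frames (one row per DCE: dce_id, chrom, start, end, label, partners,
#' jaccard); \code{pairs} records the overlap graph; \code{counts} tabulates
#' labels per side with ratios.
#'
#' @export
setClass("DynamicsReport", representation(
    refLabels = "data.frame",
    queryLabels = "data.frame",
    pairs = "data.frame",
    counts = "data.frame",
    params = "list"
))

.DCE_LABELS <- c("intact", "depleted", "emerged", "split", "merged",
                 "expanded", "contracted")

setValidity("DynamicsReport", function(object) {
    lab <- c(object@refLabels$label, object@queryLabels$label)
    if (any(!lab %in% .DCE_LABELS))
        return("labels must be one of the seven dynamics categories")
    if (anyNA(lab)) return("every DCE must receive exactly one label")
    TRUE
})
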