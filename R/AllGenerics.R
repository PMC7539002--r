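#' @rdname MaskedCorrelation-class
#' @param x a dcescan object.
#' @export
setGeneric("maskedRho", function(x) standardGeneric("maskedRho"))

#' @rdname MaskedCorrelation-class
#' @export
setGeneric("rhoMatrix", function(x) standardGeneric("rhoMatrix"))

#' @rdname MaskedCorrelation-class
#' @export
setGeneric("pvalMatrix", function(x) standardGeneric("pvalMatrix"))

#' @rdname MaskedCorrelation-class
#' @export
setGeneric("binIndex", function(x) standardGeneric("binIndex"))

#' @rdname DCESet-class
#' @export
setGeneric("domains", function(x) standardGeneric("domains"))

#' @rdname DCESet-class
#' @export
setGeneric("dceGroup", function(x) standardGeneric("dceGroup"))

#' @rdname DCESet-class
#' @export
setGeneric("dceParams", function(x) standardGeneric("dceParams"))

#' @rdname BinSignal-class
#' @export
setGeneric("signalValues", function(x) standardGeneric("signalValues"))

#' @rdname BinSignal-class
#' @export
setGeneric("smoothedSignal", function(x) standardGeneric("smoothedSignal"))

#' @rdname DynamicsReport-class
#' @export
setGeneric("refLabels", function(x) standardGeneric("refLabels"))

#' @rdname DynamicsReport-class
#' @export
setGeneric("queryLabels", function(x) standardGeneric("queryLabels"))

#' @rdname DynamicsReport-class
#' @export
setGeneric("dynamicsCounts", function(x) standardGeneric("dynamicsCounts"))

#' @rdname DynamicsReport-class
#' @export
setGeneric("overlapPairs", function(x) standardGeneric("overlapPairs"))

setMethod("maskedRho", "MaskedCorrelation", function(x) x@maskedRho)
setMethod("rhoMatrix", "MaskedCorrelation", function(x) x@rho)
setMethod("pvalMatrix", "MaskedCorrelation", function(x) x@pval)
setMethod("binIndex", "MaskedCorrelation", function(x) x@binIndex)
setMethod("binIndex", "BinSignal", function(x) x@binIndex)
setMethod("domains", "DCESet", function(x) x@domains)
setMethod("dceGroup", "DCESet", function(x) x@group)
setMethod("dceGroup", "MaskedCorrelation", function(x) x@group)
setMethod("dceParams", "DCESet", function(x) x@params)
setMethod("signalValues", "BinSignal", function(x) x@values)
setMethod("smoothedSignal", "BinSignal", function(x) x@smoothed)
setMethod("refLabels", "DynamicsReport", function(x) x@refLabels)
setMethod("queryLabels", "DynamicsReport", function(x) x@queryLabels)
setMethod("dynamicsCounts", "DynamicsReport", function(x) x@counts)
setMethod("overlapPairs", "DynamicsReport", function(x) x@pairs)

#' @export
setMethod("length", "DCESet", function(x) length(x@domains))

setMethod("show", "MaskedCorrelation", function(object) {
    n <- nrow(object@rho)
    off <- object@pval[upper.tri(object@pval)]
    kept <- if (length(off)) mean(off <= object@alpha, na.rm = TRUE) else NA
    cat("MaskedCorrelation:", object@chrom, "/", object@group, "\n")
    cat("  bins:", n, " nPerm:", object@nPerm, " alpha:", object@alpha,
        " sided:", object@sided, "\n")
    cat(sprintf("  retained off-diagonal fraction: %.4f\n", kept))
})

setMethod("show", "BinSignal", function(object) {
    cat("BinSignal:", object@chrom, "/", object@group,
        " (w =", object@w, ")\n")
    cat(sprintf("  %d bins; signal mean %.3f [%.3f, %.3f]\n",
                length(object@values), mean(object@values),
                min(object@values), max(object@values)))
})

setMethod("show", "DCESet", function(object) {
    gr <- object@domains
    cat("DCESet:", object@group, "-", length(gr), "domains\n")
    if (length(gr)) {
        cat("  chromosomes:",
            paste(unique(as.character(seqnames(gr))), collapse = ", "), "\n")
        cat(sprintf("  span: median %.0f bp, total %.0f bp\n",
                    stats::median(width(gr)), sum(as.numeric(width(gr)))))
    }
})

setMethod("show", "DynamicsReport", function(object) {
    cat("DynamicsReport:", nrow(object@refLabels), "reference /",
        nrow(object@queryLabels), "query DCEs\n")
    print(object@counts)
})
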