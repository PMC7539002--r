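# Coerce DCESet / GRanges input to GRanges.
.asDomainGR <- function(x) {
    if (is(x, "DCESet")) domains(x) else x
}

#' Jaccard index of two genomic intervals
#'
#' Intersection over union in base pairs; 0 when disjoint. Both intervals
#' must be non-empty and on the same chromosome.
#'
#' @param a,b length-1 GRanges.
#' @return numeric in [0, 1].
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150))
#' jaccardIndex(a, b)  # 50 / 150
#' @export
jaccardIndex <- function(a, b) {
    if (length(a) != 1L || length(b) != 1L)
        stop("jaccardIndex expects single intervals")
    if (width(a) < 1L || width(b) < 1L) stop("zero-length interval")
    if (as.character(seqnames(a)) != as.character(seqnames(b)))
        stop("intervals must be on the same chromosome")
    inter <- max(0L, min(end(a), end(b)) - max(start(a), start(b)) + 1L)
    inter / (width(a) + width(b) - inter)
}

# Partition [1, chromLength] into the sorted intervals of gr plus the
# complementary background segments. Bookended domains stay distinct
# segments; only true overlaps are collapsed.
.partitionSegments <- function(gr, chromLength) {
    gr <- reduce(sort(.asDomainGR(gr)), min.gapwidth = 0L)
    if (length(gr) && max(end(gr)) > chromLength)
        stop("intervals exceed the stated chromosome length")
    st <- start(gr); en <- end(gr)
    bounds <- sort(unique(c(1L, st, en + 1L, chromLength + 1L)))
    bounds <- bounds[bounds <= chromLength + 1L]
    data.frame(start = bounds[-length(bounds)],
               end = bounds[-1] - 1L)
}

#' BP distance between two chromosome segmentations
#'
#' The segmentation-comparison metric that accounts for relative segment
#' sizes: both interval sets are completed into partitions of
#' [1, chromLength] (uncovered regions become background segments), and
#' d = (1/N) * sum over overlapping segment pairs of
#' o * (1 - o / max(|a|, |b|)), with o the pair's overlap in bp. Symmetric,
#' in [0, 1], and 0 exactly for identical partitions.
#'
#' @param segA,segB [DCESet-class] or GRanges restricted to one chromosome.
#' @param chromLength chromosome length in bp.
#' @return numeric distance in [0, 1].
#' @export
bpDistance <- function(segA, segB, chromLength) {
    .assertScalarNumber(chromLength, "chromLength")
    a <- .asDomainGR(segA); b <- .asDomainGR(segB)
    chr <- unique(c(as.character(seqnames(a)), as.character(seqnames(b))))
    if (length(chr) > 1L)
        stop("bpDistance compares segmentations of a single chromosome")
    pa <- .partitionSegments(a, chromLength)
    pb <- .partitionSegments(b, chromLength)
    ia <- IRanges(pa$start, pa$end)
    ib <- IRanges(pb$start, pb$end)
    ov <- findOverlaps(ia, ib)
    o <- width(pintersect(ia[queryHits(ov)], ib[subjectHits(ov)]))
    mx <- pmax(width(ia)[queryHits(ov)], width(ib)[subjectHits(ov)])
    sum(o * (1 - o / mx)) / chromLength
}

# Union-find over the bipartite overlap graph.
.components <- function(nRef, nQuery, pairs) {
    parent <- seq_len(nRef + nQuery)
    find <- function(i) {
        while (parent[i] != i) i <- parent[i]
        i
    }
    for (k in seq_len(nrow(pairs))) {
        a <- find(pairs$ref[k])
        b <- find(nRef + pairs$query[k])
        if (a != b) parent[b] <- a
    }
    vapply(seq_along(parent), find, integer(1))
}

# Swap-antisymmetric comparison of two interval collections: positive when
# the first is "larger" (fewer constraints to be the merged side).
.fragScore <- function(ir) {
    w <- as.numeric(width(reduce(ir)))
    c(length(w), sum(w), max(w), sum(w^2))
}

# Label one connected component of the overlap graph. Works on plain
# IRanges (a component lives on one chromosome by construction).
.labelComponent <- function(refGR, qGR, intactJaccard, tol) {
    nr <- length(refGR); nq <- length(qGR)
    if (nr == 0L) return("emerged")
    if (nq == 0L) return("depleted")
    if (nr == 1L && nq == 1L) {
        j <- jaccardIndex(refGR, qGR)
        if (j >= intactJaccard || width(qGR) == width(refGR)) return("intact")
        return(if (width(qGR) > width(refGR)) "expanded" else "contracted")
    }
    refU <- reduce(ranges(refGR)); qU <- reduce(ranges(qGR))
    qInRef <- sum(width(setdiff(qU, refU + tol))) == 0L
    rInQ <- sum(width(setdiff(refU, qU + tol))) == 0L
    if (qInRef && !rInQ) return("split")
    if (rInQ && !qInRef) return("merged")
    sa <- .fragScore(ranges(refGR)); sb <- .fragScore(ranges(qGR))
    for (i in seq_along(sa)) {
        if (sa[i] > sb[i]) return("split")
        if (sa[i] < sb[i]) return("merged")
    }
    "split"                               # fully tied degenerate component
}

#' Classify DCE dynamics between a reference and a query segmentation
#'
#' Builds the overlap graph between the two sets and labels every domain of
#' both sets with exactly one of the seven categories: reference domains
#' without query overlap are depleted, query domains without reference
#' overlap are emerged; a reference domain fragmenting into several query
#' domains is a split (the fragments inherit the label), several reference
#' domains joining into one query domain is a merge; remaining one-to-one
#' pairs are intact when their Jaccard index reaches \code{intactJaccard},
#' otherwise expanded (query longer) or contracted (query shorter).
#' Many-to-many components are resolved towards split or merged by comparing
#' which side is the fragmented one (the side whose union fits inside the
#' other, with \code{tol} bp of slack, then by piece count and total bp).
#'
#' @param ref,query [DCESet-class] objects (or GRanges) with internally
#'   non-overlapping domains.
#' @param intactJaccard Jaccard cutoff for the intact label.
#' @param minOverlapFrac overlaps smaller than this fraction of the smaller
#'   domain are ignored when building the graph (guards against 1-bp
#'   contacts; default 0 keeps every >= 1 bp overlap).
#' @param tol containment slack in bp for the split/merged resolution
#'   (default: one 10 kb bin).
#' @return a [DynamicsReport-class].
#' @export
classifyDCEs <- function(ref, query, intactJaccard = 0.8,
                         minOverlapFrac = 0, tol = 10000) {
    refGR <- .asDomainGR(ref); qGR <- .asDomainGR(query)
    for (gr in list(refGR, qGR))
        if (length(gr) > 1 &&
            length(findOverlaps(gr, drop.self = TRUE,
                                drop.redundant = TRUE)) > 0)
            stop("domains within one set must not overlap")
    ov <- findOverlaps(refGR, qGR)
    pairs <- data.frame(ref = queryHits(ov), query = subjectHits(ov))
    if (nrow(pairs)) {
        ow <- pmin(end(refGR)[pairs$ref], end(qGR)[pairs$query]) -
            pmax(start(refGR)[pairs$ref], start(qGR)[pairs$query]) + 1L
        minw <- pmin(width(refGR)[pairs$ref], width(qGR)[pairs$query])
        keep <- ow >= pmax(1, minOverlapFrac * minw)
        pairs <- pairs[keep, , drop = FALSE]
        ow <- ow[keep]
        pairs$overlap_bp <- ow
        pairs$jaccard <- ow / (width(refGR)[pairs$ref] +
                               width(qGR)[pairs$query] - ow)
    } else {
        pairs$overlap_bp <- integer(0)
        pairs$jaccard <- numeric(0)
    }
    comp <- .components(length(refGR), length(qGR), pairs)
    refComp <- comp[seq_along(refGR)]
    qComp <- comp[length(refGR) + seq_along(qGR)]
    refLab <- rep(NA_character_, length(refGR))
    qLab <- rep(NA_character_, length(qGR))
    for (cc in unique(comp)) {
        ri <- which(refComp == cc); qi <- which(qComp == cc)
        lab <- .labelComponent(refGR[ri], qGR[qi], intactJaccard, tol)
        refLab[ri] <- lab
        qLab[qi] <- lab
    }
    .labelDf <- function(gr, lab, otherIds, side) {
        partners <- vapply(seq_along(gr), function(i) {
            p <- if (side == "ref") pairs$query[pairs$ref == i]
                 else pairs$ref[pairs$query == i]
            paste(otherIds[p], collapse = ",")
        }, character(1))
        bestJ <- vapply(seq_along(gr), function(i) {
            j <- if (side == "ref") pairs$jaccard[pairs$ref == i]
                 else pairs$jaccard[pairs$query == i]
            if (length(j)) max(j) else NA_real_
        }, numeric(1))
        data.frame(dce_id = .dceIds(gr), chrom = as.character(seqnames(gr)),
                   start = start(gr), end = end(gr), label = lab,
                   partners = partners, jaccard = bestJ,
                   stringsAsFactors = FALSE)
    }
    refIds <- .dceIds(refGR); qIds <- .dceIds(qGR)
    refDf <- .labelDf(refGR, refLab, qIds, "ref")
    qDf <- .labelDf(qGR, qLab, refIds, "query")
    cnt <- data.frame(label = .DCE_LABELS,
                      ref = as.integer(table(factor(refLab, .DCE_LABELS))),
                      query = as.integer(table(factor(qLab, .DCE_LABELS))))
    cnt$all <- cnt$ref + cnt$query
    tot <- sum(cnt$all)
    cnt$ratio <- if (tot > 0) cnt$all / tot else 0
    new("DynamicsReport", refLabels = refDf, queryLabels = qDf,
        pairs = cbind(pairs,
                      ref_id = refIds[pairs$ref],
                      query_id = qIds[pairs$query]),
        counts = cnt,
        params = list(intactJaccard = intactJaccard,
                      minOverlapFrac = minOverlapFrac, tol = tol))
}

.dceIds <- function(gr) {
    if (!is.null(gr$dce_id)) as.character(gr$dce_id)
    else if (length(gr)) paste0("dce_", seq_len(length(gr)))
    else character(0)
}

#' Extract disruptor genes of one split event
#'
#' Disruptors are the genes that lie inside a reference (healthy) domain
#' labelled split, overlap none of the query (patient) domains, and whose
#' span intersects the gap(s) between the query fragments inside the
#' reference domain — the locus of the split.
#'
#' @param refDce length-1 GRanges: the split reference domain.
#' @param query the query [DCESet-class] or GRanges.
#' @param genes annotation GRanges with \code{gene_name}.
#' @return list with \code{genes} (disruptor names), \code{gaps} (GRanges of
#'   the split loci) and \code{fragments} (ids of the flanking query
#'   domains).
#' @export
findDisruptors <- function(refDce, query, genes) {
    qGR <- .asDomainGR(query)
    frag <- qGR[overlapsAny(qGR, refDce)]
    if (length(frag) < 2L)
        stop("reference domain is not split (needs >= 2 overlapping query ",
             "domains)")
    inRef <- sort(reduce(restrict(frag, start = start(refDce),
                                  end = end(refDce))))
    gaps <- setdiff(GRanges(seqnames(refDce),
                            IRanges(min(start(inRef)), max(end(inRef)))),
                    inRef)
    hit <- overlapsAny(genes, refDce) &
        !overlapsAny(genes, qGR) &
        overlapsAny(genes, gaps)
    list(genes = as.character(genes$gene_name[hit]), gaps = gaps,
         fragments = .dceIds(frag))
}

#' Disruptor genes for every split event of a comparison
#'
#' @param report a [DynamicsReport-class] from [classifyDCEs()].
#' @param ref,query the two segmentations that were compared.
#' @param genes annotation GRanges.
#' @return data.frame (ref_dce, fragments, gene) with one row per disruptor.
#' @export
disruptorTable <- function(report, ref, query, genes) {
    refGR <- .asDomainGR(ref)
    lab <- refLabels(report)
    out <- list()
    for (i in which(lab$label == "split")) {
        d <- tryCatch(findDisruptors(refGR[i], query, genes),
                      error = function(e) NULL)
        if (is.null(d) || length(d$genes) == 0L) next
        out[[length(out) + 1L]] <- data.frame(
            ref_dce = lab$dce_id[i],
            fragments = paste(d$fragments, collapse = ","),
            gene = d$genes, stringsAsFactors = FALSE)
    }
    if (length(out) == 0L)
        return(data.frame(ref_dce = character(0), fragments = character(0),
                          gene = character(0)))
    do.call(rbind, out)
}

#' Coverage summary of a DCE segmentation
#'
#' Per-chromosome and genome-wide fraction of eligible (expressed) bins that
#' fall inside domains, plus counts and the domain size distribution.
#'
#' @param dce a [DCESet-class] or GRanges.
#' @param eligible GRanges of eligible bins (see [eligibleBins()]).
#' @return list with \code{perChrom} (data.frame), \code{genomeFraction},
#'   \code{nDce} and \code{sizesBp}.
#' @export
coverageStats <- function(dce, eligible) {
    gr <- .asDomainGR(dce)
    chroms <- unique(as.character(seqnames(eligible)))
    per <- do.call(rbind, lapply(chroms, function(ch) {
        el <- eligible[as.character(seqnames(eligible)) == ch]
        inDce <- sum(overlapsAny(el, gr))
        data.frame(chrom = ch, eligible_bins = length(el),
                   bins_in_dce = inDce,
                   fraction = inDce / length(el))
    }))
    list(perChrom = per,
         genomeFraction = sum(per$bins_in_dce) / sum(per$eligible_bins),
         nDce = length(gr),
         sizesBp = as.numeric(width(gr)))
}
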