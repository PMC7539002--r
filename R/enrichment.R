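# Uniform random non-overlapping arrangement of interval sizes (in eligible
# bins) on an axis of nElig bins: draw the gap composition uniformly via a
# sorted sample without replacement, shuffling size order first.
.placeSizes <- function(sizes, nElig) {
    m <- length(sizes)
    free <- nElig - sum(sizes)
    if (free < 0) stop("intervals do not fit the eligible territory")
    sizes <- sizes[sample.int(m)]
    picks <- sort(sample.int(free + m, m))
    gaps <- diff(c(0L, picks)) - 1L
    starts <- cumsum(gaps + c(0L, sizes[-m])) + 1L
    data.frame(start = starts, size = sizes)
}

# Randomly re-place the domains of a segmentation within their chromosomes,
# restricted to eligible-bin territory, preserving sizes (in eligible bins)
# and chromosome assignment. Returns a GRanges of the placed intervals in
# genomic coordinates (span of the covered eligible bins).
.randomPlacement <- function(dceGR, eligible) {
    out <- list()
    for (ch in unique(as.character(seqnames(dceGR)))) {
        el <- sort(eligible[as.character(seqnames(eligible)) == ch])
        d <- dceGR[as.character(seqnames(dceGR)) == ch]
        sizes <- countOverlaps(d, el)
        sizes <- pmax(sizes, 1L)
        pl <- .placeSizes(sizes, length(el))
        gr <- GRanges(ch, IRanges(start(el)[pl$start],
                                  end(el)[pl$start + pl$size - 1L]))
        stopifnot(isDisjoint(gr))                     # non-overlap audit
        out[[ch]] <- gr
    }
    sort(suppressWarnings(do.call(c, unname(out))))
}

# Shared permutation machinery: observed statistic vs. statistics of nPerm
# random placements. Empirical p uses the (k+1)/(n+1) estimator, two-sided
# reported as the doubled smaller tail capped at 1.
.placementTest <- function(dceGR, eligible, stat, nPerm, seed) {
    obs <- stat(dceGR)
    set.seed(seed)
    null <- vapply(seq_len(nPerm),
                   function(r) stat(.randomPlacement(dceGR, eligible)),
                   numeric(1))
    pEnrich <- (sum(null >= obs) + 1) / (nPerm + 1)
    pDeplete <- (sum(null <= obs) + 1) / (nPerm + 1)
    sdv <- stats::sd(null)
    list(observed = obs, nullMean = mean(null), nullSd = sdv,
         z = if (isTRUE(sdv > 0)) (obs - mean(null)) / sdv else NA_real_,
         p.enrich = pEnrich, p.deplete = pDeplete,
         p.value = min(1, 2 * min(pEnrich, pDeplete)))
}

#' Permutation enrichment of a gene set in a DCE subset
#'
#' Counts how many genes of the set overlap the domains and compares the
#' count against a null obtained by randomly re-placing the domain intervals
#' within their chromosomes, uniformly over the eligible (expressed-bin)
#' territory, preserving sizes and avoiding overlap. Gene overlap uses the
#' annotated gene span (\code{anchor = "span"}) or the 5' end
#' (\code{anchor = "tss"}).
#'
#' @param dce a [DCESet-class] or GRanges (e.g. all domains of one dynamics
#'   category).
#' @param geneSet character vector of gene names.
#' @param genes annotation GRanges with \code{gene_name}.
#' @param eligible GRanges of eligible bins (see [eligibleBins()]).
#' @param nPerm permutation rounds.
#' @param seed RNG seed.
#' @param anchor gene-overlap rule.
#' @return list with observed count, null mean/sd, z, directional and
#'   two-sided empirical p-values.
#' @export
genesetEnrichment <- function(dce, geneSet, genes, eligible, nPerm = 1000,
                              seed = 1L, anchor = c("span", "tss")) {
    anchor <- match.arg(anchor)
    dceGR <- .asDomainGR(dce)
    g <- genes[as.character(genes$gene_name) %in% geneSet]
    if (anchor == "tss") g <- resize(g, 1L, fix = "start")
    covered <- unique(as.character(seqnames(eligible)))
    g <- g[as.character(seqnames(g)) %in% covered]
    if (length(g) == 0L)
        stop("no gene of the set lies on a covered chromosome")
    if (length(dceGR) == 0L)
        return(list(observed = 0L, nullMean = 0, nullSd = 0, z = NA_real_,
                    p.enrich = 1, p.deplete = 1 / (nPerm + 1), p.value = 1,
                    direction = "depletion"))
    res <- .placementTest(dceGR, eligible,
                          function(gr) sum(overlapsAny(g, gr)), nPerm, seed)
    res$direction <- if (res$p.enrich <= res$p.deplete) "enrichment"
                     else "depletion"
    res
}

#' Permutation enrichment of DCEs in the labels of an interval track
#'
#' For each track label the observed bp overlap with the domains is compared
#' to the same randomized-placement null as [genesetEnrichment()]; p-values
#' across labels are Benjamini-Hochberg corrected. Labels without intervals
#' on any covered chromosome are reported untestable (NA) rather than zero.
#'
#' @param dce a [DCESet-class] or GRanges.
#' @param track GRanges with a \code{label} metadata column (e.g. Hi-C
#'   subcompartments A1/A2/B1-B4, ATAC gain/loss).
#' @param eligible GRanges of eligible bins.
#' @param nPerm permutation rounds.
#' @param seed RNG seed.
#' @return data.frame, one row per label: observed bp, null mean/sd, z, raw
#'   and BH-adjusted two-sided p.
#' @export
trackEnrichment <- function(dce, track, eligible, nPerm = 1000, seed = 1L) {
    dceGR <- .asDomainGR(dce)
    covered <- unique(as.character(seqnames(eligible)))
    labels <- unique(as.character(track$label))
    rows <- lapply(seq_along(labels), function(k) {
        tr <- track[as.character(track$label) == labels[k]]
        tr <- tr[as.character(seqnames(tr)) %in% covered]
        if (length(tr) == 0L)
            return(data.frame(label = labels[k], testable = FALSE,
                              observed_bp = NA_real_, null_mean = NA_real_,
                              null_sd = NA_real_, z = NA_real_,
                              p.value = NA_real_))
        res <- .placementTest(dceGR, eligible, function(gr)
            sum(as.numeric(width(intersect(gr, tr)))),
            nPerm, deriveSeed(seed, k))
        data.frame(label = labels[k], testable = TRUE,
                   observed_bp = res$observed, null_mean = res$nullMean,
                   null_sd = res$nullSd, z = res$z, p.value = res$p.value)
    })
    out <- do.call(rbind, rows)
    out$p.adj <- NA_real_
    out$p.adj[out$testable] <- stats::p.adjust(out$p.value[out$testable],
                                               method = "BH")
    out
}

# A link is nested in a segmentation when one single domain contains both
# the promoter position and the whole enhancer interval.
.nestedIn <- function(links, dceGR) {
    prom <- GRanges(links$chrom,
                    IRanges(links$promoter_pos, links$promoter_pos))
    enh <- GRanges(links$chrom, IRanges(links$enh_start, links$enh_end))
    op <- findOverlaps(prom, dceGR, type = "within")
    oe <- findOverlaps(enh, dceGR, type = "within")
    key <- paste(queryHits(op), subjectHits(op)) %in%
           paste(queryHits(oe), subjectHits(oe))
    seq_len(nrow(links)) %in% queryHits(op)[key]
}

#' Enhancer-promoter link disruption between two segmentations
#'
#' A link is nested when its promoter and its enhancer fall inside the same
#' domain. Links nested in the reference set are evaluable; an evaluable link
#' is disrupted when it is no longer nested in the query set (split or
#' depletion of the hosting domain). Links never nested in the reference are
#' excluded from the denominator. Malformed rows (missing coordinates,
#' inverted enhancer intervals) are skipped with a warning count.
#'
#' @param links data.frame of links (see [readEpLinks()]).
#' @param ref,query [DCESet-class] objects or GRanges.
#' @return list with \code{perLink} (the links plus nested_ref, nested_query,
#'   status), \code{fractionDisrupted}, \code{disruptedGenes} and
#'   \code{nSkipped}.
#' @export
epDisruption <- function(links, ref, query) {
    refGR <- .asDomainGR(ref); qGR <- .asDomainGR(query)
    bad <- is.na(links$chrom) | is.na(links$promoter_pos) |
        is.na(links$enh_start) | is.na(links$enh_end) |
        links$enh_end < links$enh_start
    if (any(bad)) warning(sum(bad), " malformed links skipped")
    lk <- links[!bad, , drop = FALSE]
    nestedRef <- .nestedIn(lk, refGR)
    nestedQuery <- .nestedIn(lk, qGR)
    status <- ifelse(!nestedRef, "not_evaluable",
              ifelse(nestedQuery, "retained", "disrupted"))
    perLink <- cbind(lk, nested_ref = nestedRef,
                     nested_query = nestedQuery, status = status)
    nEval <- sum(nestedRef)
    list(perLink = perLink,
         fractionDisrupted = if (nEval > 0)
             sum(status == "disrupted") / nEval else NA_real_,
         disruptedGenes = unique(lk$gene[status == "disrupted"]),
         nSkipped = sum(bad))
}

#' Shannon entropy of cell-type proportions (bits)
#'
#' H = -sum p_i log2 p_i, with zero proportions contributing 0. Maximal
#' (log2 n) at the uniform composition, 0 when a single cell type has all
#' the mass.
#'
#' @param p numeric vector of proportions (non-negative, summing to 1 within
#'   1e-6).
#' @return entropy in bits.
#' @examples
#' shannonEntropy(rep(0.25, 4))         # 2 bits
#' shannonEntropy(c(0.5, 0.25, 0.25))   # 1.5 bits
#' @export
shannonEntropy <- function(p) {
    if (any(p < 0)) stop("negative proportion")
    if (abs(sum(p) - 1) > 1e-6) stop("proportions must sum to 1")
    p <- p[p > 0]
    -sum(p * log2(p))
}

#' Rank-sum comparison of two entropy distributions
#'
#' Two-sided Wilcoxon-Mann-Whitney test; exact enumeration (tie-safe) when
#' both groups have at most 8 values, tie-corrected normal approximation
#' otherwise.
#'
#' @param healthy,patient numeric vectors (>= 3 values each).
#' @return two-sided p-value.
#' @export
entropyGroupTest <- function(healthy, patient) {
    if (length(healthy) < 3L || length(patient) < 3L)
        stop("need at least 3 values per group")
    rankSumTest(healthy, patient, alternative = "two.sided")$p.value
}
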