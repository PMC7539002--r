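#' Default DCE-calling configuration
#'
#' Central defaults: 10 kb bins, window w = 3 bins, signal threshold 0.25
#' (the genome-average signal of the reference/healthy group), boundary and
#' mask alpha 0.05, 1000 permutation rounds, fusion limited to gaps of at
#' most 2 low-signal bins, at most 2 intervening low bins per fused chain and
#' at most 3 fused domains, minimum domain size 2 bins.
#'
#' @param binSize bin width in bp.
#' @param w window size in bins for the bin signal and boundary tests.
#' @param threshold bin-signal threshold for qualifying minima and fusion.
#' @param alpha boundary-test significance level.
#' @param maskAlpha permutation-mask significance level.
#' @param nPerm permutation rounds for the correlation mask.
#' @param minSize minimum domain size in bins before discard.
#' @param maxGapBins maximal fusion gap in bins.
#' @param maxLowBins maximal cumulative intervening low-signal bins per chain.
#' @param maxChain maximal number of domains fused into one.
#' @param sided sidedness of the permutation mask test.
#' @param assignment gene-to-bin assignment rule (see [binExpression()]).
#' @param intactJaccard Jaccard cutoff for the intact dynamics label.
#' @param seed master seed; chromosome streams are derived from it.
#' @return named list of parameters.
#' @export
dceConfig <- function(binSize = 10000, w = 3, threshold = 0.25,
                      alpha = 0.05, maskAlpha = 0.05, nPerm = 1000,
                      minSize = 2, maxGapBins = 2, maxLowBins = 2,
                      maxChain = 3, sided = "two", assignment = "span",
                      intactJaccard = 0.8, seed = 1L) {
    list(binSize = binSize, w = as.integer(w), threshold = threshold,
         alpha = alpha, maskAlpha = maskAlpha, nPerm = as.integer(nPerm),
         minSize = as.integer(minSize), maxGapBins = as.integer(maxGapBins),
         maxLowBins = as.integer(maxLowBins), maxChain = as.integer(maxChain),
         sided = sided, assignment = assignment,
         intactJaccard = intactJaccard, seed = as.integer(seed))
}

#' Bin signal: local average cross-correlation along a chromosome
#'
#' Two juxtaposed windows of \code{w} bins slide along the chromosome with
#' single-bin displacement; at each admissible position i (the downstream-most
#' bin of the upstream window) the signal is the mean of the w x w block of
#' masked correlations between the two windows (cross entries only; masked
#' zeros count as 0). Positions within w-1 of either chromosome end have no
#' full window pair and inherit the nearest admissible value; they cannot
#' host minima.
#'
#' @param mc a [MaskedCorrelation-class] (needs >= 2w bins).
#' @param w window size in bins.
#' @return a [BinSignal-class] with the raw signal and a cubic
#'   smoothing-spline fit (smoothing parameter by generalized
#'   cross-validation) evaluated at the bin positions.
#' @export
binSignal <- function(mc, w = 3L) {
    w <- as.integer(w)
    m <- maskedRho(mc)
    m[is.na(m)] <- 0
    n <- nrow(m)
    if (n < 2L * w)
        stop("chromosome has fewer than 2w surviving bins (", n, " < ",
             2L * w, ")")
    sig <- rep(NA_real_, n)
    for (i in w:(n - w))
        sig[i] <- mean(m[(i - w + 1L):i, (i + 1L):(i + w)])
    sig[seq_len(w - 1L)] <- sig[w]
    sig[(n - w + 1L):n] <- sig[n - w]
    smoothed <- tryCatch({
        fit <- stats::smooth.spline(seq_len(n), sig)
        stats::predict(fit, seq_len(n))$y
    }, error = function(e) sig)
    new("BinSignal", chrom = mc@chrom, group = mc@group, w = w,
        values = sig, smoothed = smoothed, binIndex = mc@binIndex)
}

# Strict local minima of a numeric vector: slope changes sign from negative
# to positive; plateau minima take the leftmost position. Endpoints are
# never minima.
.localMinima <- function(s) {
    n <- length(s)
    if (n < 3L) return(integer(0))
    d <- diff(s)
    sgn <- sign(d)
    # carry the last non-zero slope forward/backward across plateaus
    lastNz <- sgn
    for (i in seq_len(n - 1L)[-1])
        if (lastNz[i] == 0) lastNz[i] <- lastNz[i - 1L]
    nextNz <- sgn
    for (i in rev(seq_len(n - 2L)))
        if (nextNz[i] == 0) nextNz[i] <- nextNz[i + 1L]
    out <- integer(0)
    for (i in 2:(n - 1L)) {
        if (lastNz[i - 1L] < 0 && nextNz[i] > 0 && sgn[i - 1L] != 0)
            out <- c(out, i)
    }
    out
}

#' Detect candidate boundaries and initial domains
#'
#' Local minima of the smoothed signal whose smoothed value lies below
#' \code{threshold} become candidate boundaries. Candidate domains are the
#' segments between consecutive qualifying minima (the flanking minimum bins
#' are included; boundary refinement chops them away), kept when the smoothed
#' signal inside rises above \code{threshold} anywhere. A constant or
#' everywhere-sub-threshold signal yields no domains. Edge positions without
#' a full window pair cannot open domains on their own (they inherit interior
#' signal values).
#'
#' @param sig a [BinSignal-class].
#' @param threshold qualifying-minimum / domain-signal threshold.
#' @return list with \code{domains} (data.frame start, end on the
#'   surviving-bin axis) and \code{minima} (positions).
#' @export
detectMinima <- function(sig, threshold = 0.25) {
    s <- smoothedSignal(sig)
    n <- length(s)
    if (max(s) == min(s))          # degenerate flat signal: nothing to call
        return(list(domains = data.frame(start = integer(0),
                                         end = integer(0)),
                    minima = integer(0)))
    mins <- .localMinima(s)
    mins <- mins[s[mins] < threshold]
    bounds <- c(1L, mins, n)
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1]
    keep <- vapply(seq_along(starts), function(k) {
        seg <- starts[k]:ends[k]
        length(seg) >= 2L && max(s[seg]) > threshold
    }, logical(1))
    list(domains = data.frame(start = starts[keep], end = ends[keep]),
         minima = mins)
}

# Split candidate domains wherever two consecutive surviving bins are more
# than maxRun grid bins apart (prevents domains bridging long runs of
# missing bins / gene deserts).
.splitAtMissingRuns <- function(domains, binIndexMap, maxRun = 2L) {
    if (nrow(domains) == 0L) return(domains)
    out <- list()
    for (k in seq_len(nrow(domains))) {
        s <- domains$start[k]; e <- domains$end[k]
        if (e <= s) { out[[length(out) + 1L]] <- c(s, e); next }
        gaps <- diff(binIndexMap[s:e]) - 1L
        cut <- which(gaps > maxRun)
        st <- c(s, s + cut)
        en <- c(s + cut - 1L, e)
        for (j in seq_along(st))
            out[[length(out) + 1L]] <- c(st[j], en[j])
    }
    df <- as.data.frame(do.call(rbind, out))
    names(df) <- c("start", "end")
    df[df$end > df$start, , drop = FALSE]
}

# One boundary test. Within: all pairwise masked correlations among the (up
# to) w domain bins adjacent to the boundary. Between: the cross block of
# masked correlations spanning the boundary (truncated at the chromosome
# edge). A boundary with no outside bins is untestable and passes (p = NA).
.testBoundary <- function(m, s, e, w, side) {
    n <- nrow(m)
    if (side == "left") {
        wb <- s:min(e, s + w - 1L)
        ob <- if (s > 1L) max(1L, s - w):(s - 1L) else integer(0)
    } else {
        wb <- max(s, e - w + 1L):e
        ob <- if (e < n) (e + 1L):min(n, e + w) else integer(0)
    }
    if (length(ob) == 0L) return(NA_real_)
    within <- upperTri(m[wb, wb, drop = FALSE])
    between <- as.vector(m[ob, wb, drop = FALSE])
    if (length(within) == 0L) return(1)
    rankSumTest(within, between, alternative = "greater")$p.value
}

#' Statistically validate and refine domain boundaries
#'
#' Each boundary is tested with a one-sided rank-sum test comparing the
#' pairwise ("within") correlations among the w domain bins adjacent to the
#' boundary against the w x w "in-between" cross block spanning it. While a
#' boundary fails (p > alpha) and the domain is longer than \code{minSize}
#' bins, that boundary is chopped by one bin towards the domain centre and
#' retested; domains still failing at \code{minSize} are discarded.
#' Chromosome-edge boundaries with no outside bins are untestable and pass
#' with p = NA.
#'
#' @param domains data.frame (start, end) from [detectMinima()].
#' @param mc the [MaskedCorrelation-class] the signal was computed from.
#' @param w window size in bins.
#' @param alpha boundary significance level.
#' @param minSize minimum domain size in bins.
#' @return data.frame (start, end, left_p, right_p) of surviving domains.
#' @export
evaluateBoundaries <- function(domains, mc, w = 3L, alpha = 0.05,
                               minSize = 2L) {
    m <- maskedRho(mc)
    m[is.na(m)] <- 0
    out <- list()
    for (k in seq_len(nrow(domains))) {
        s <- domains$start[k]; e <- domains$end[k]
        lp <- rp <- NA_real_
        ok <- FALSE
        while (e - s + 1L >= minSize) {
            lp <- .testBoundary(m, s, e, w, "left")
            if (!is.na(lp) && lp > alpha) { s <- s + 1L; next }
            rp <- .testBoundary(m, s, e, w, "right")
            if (!is.na(rp) && rp > alpha) { e <- e - 1L; next }
            ok <- TRUE
            break
        }
        if (ok)
            out[[length(out) + 1L]] <-
                data.frame(start = s, end = e, left_p = lp, right_p = rp)
    }
    if (length(out) == 0L)
        return(data.frame(start = integer(0), end = integer(0),
                          left_p = numeric(0), right_p = numeric(0)))
    res <- do.call(rbind, out)
    res <- res[order(res$start), , drop = FALSE]
    # candidates share their flanking minimum bin; resolve residual overlaps
    if (nrow(res) > 1L) {
        drop <- logical(nrow(res))
        for (k in 2:nrow(res)) {
            prev <- max(which(!drop[seq_len(k - 1L)]))
            if (res$start[k] <= res$end[prev]) {
                res$start[k] <- res$end[prev] + 1L
                if (res$end[k] - res$start[k] + 1L < 2L) drop[k] <- TRUE
            }
        }
        res <- res[!drop, , drop = FALSE]
    }
    rownames(res) <- NULL
    res
}

#' Fuse neighbouring validated domains
#'
#' A greedy left-to-right scan merges consecutive domains when (a) they are
#' separated by at most \code{maxGapBins} bins, all with bin signal below
#' \code{threshold}, and (b) the cumulative number of intervening low-signal
#' bins within the fused chain stays at most \code{maxLowBins} — hence no
#' more than \code{maxChain} domains fuse into one. Gaps are counted on the
#' genomic grid (missing bins included), so a fused domain never bridges more
#' than \code{maxGapBins} missing bins. Fused domains keep the outermost
#' original boundary p-values; the mean signal is recomputed over the fused
#' span.
#'
#' @param domains data.frame from [evaluateBoundaries()].
#' @param sig the [BinSignal-class] of the chromosome.
#' @param threshold low-signal threshold.
#' @param maxGapBins,maxLowBins,maxChain fusion limits.
#' @return data.frame (start, end, left_p, right_p, mean_signal).
#' @export
fuseDomains <- function(domains, sig, threshold = 0.25, maxGapBins = 2L,
                        maxLowBins = 2L, maxChain = 3L) {
    v <- signalValues(sig)
    idx <- binIndex(sig)
    if (nrow(domains) == 0L) {
        domains$mean_signal <- numeric(0)
        return(domains)
    }
    res <- domains[1, , drop = FALSE]
    chainLow <- 0L
    chainCount <- 1L
    for (k in seq_len(nrow(domains))[-1]) {
        cur <- nrow(res)
        gapBins <- if (domains$start[k] > res$end[cur] + 1L)
            (res$end[cur] + 1L):(domains$start[k] - 1L) else integer(0)
        genomicGap <- idx[domains$start[k]] - idx[res$end[cur]] - 1L
        fuse <- genomicGap <= maxGapBins &&
            all(v[gapBins] < threshold) &&
            chainLow + genomicGap <= maxLowBins &&
            chainCount < maxChain
        if (fuse) {
            res$end[cur] <- domains$end[k]
            res$right_p[cur] <- domains$right_p[k]
            chainLow <- chainLow + genomicGap
            chainCount <- chainCount + 1L
        } else {
            res <- rbind(res, domains[k, , drop = FALSE])
            chainLow <- 0L
            chainCount <- 1L
        }
    }
    res$mean_signal <- vapply(seq_len(nrow(res)), function(i)
        mean(v[res$start[i]:res$end[i]]), numeric(1))
    rownames(res) <- NULL
    res
}

# Full single-chromosome call; returns intermediates for tuning/inspection.
.callChrom <- function(binned, samples, group, chrom, config) {
    idx <- survivingBins(binned, samples, chrom)
    if (length(idx) < 2L * config$w) {
        warning("chromosome ", chrom, " skipped: fewer than 2w surviving bins")
        return(NULL)
    }
    m <- assay(binned, "meanExpr")[idx, samples, drop = FALSE]
    chromSeed <- deriveSeed(config$seed,
                            match(chrom, seqlevels(rowRanges(binned))))
    mc <- permutationMask(m, nPerm = config$nPerm, alpha = config$maskAlpha,
                          seed = chromSeed, sided = config$sided,
                          chrom = chrom, group = group, binIndexMap = idx)
    sig <- binSignal(mc, config$w)
    dm <- detectMinima(sig, config$threshold)$domains
    dm <- .splitAtMissingRuns(dm, idx, config$maxGapBins)
    vd <- evaluateBoundaries(dm, mc, config$w, config$alpha, config$minSize)
    fd <- fuseDomains(vd, sig, config$threshold, config$maxGapBins,
                      config$maxLowBins, config$maxChain)
    list(mc = mc, sig = sig, domains = fd, idx = idx)
}

# Convert per-chromosome domain tables to a DCESet.
.domainsToSet <- function(pieces, binned, group, config) {
    grid <- rowRanges(binned)
    geneList <- rowData(binned)$geneList
    grs <- list()
    for (chrom in names(pieces)) {
        p <- pieces[[chrom]]
        if (is.null(p) || nrow(p$domains) == 0L) next
        d <- p$domains
        gStart <- start(grid)[p$idx[d$start]]
        gEnd <- end(grid)[p$idx[d$end]]
        genes <- CharacterList(lapply(seq_len(nrow(d)), function(i) {
            bins <- p$idx[d$start[i]]:p$idx[d$end[i]]
            unique(unlist(geneList[bins], use.names = FALSE))
        }))
        gr <- GRanges(chrom, IRanges(gStart, gEnd),
                      dce_id = sprintf("%s_%s_%d", group, chrom,
                                       seq_len(nrow(d))),
                      start_bin = d$start, end_bin = d$end,
                      mean_signal = d$mean_signal,
                      left_p = d$left_p, right_p = d$right_p,
                      genes = genes)
        grs[[chrom]] <- gr
    }
    dom <- if (length(grs)) sort(suppressWarnings(do.call(c, unname(grs))))
           else GRanges(dce_id = character(0), start_bin = integer(0),
                        end_bin = integer(0), mean_signal = numeric(0),
                        left_p = numeric(0), right_p = numeric(0),
                        genes = CharacterList())
    new("DCESet", domains = dom, group = group, params = config)
}

#' Call domains of co-ordinated expression for one sample group
#'
#' Runs the four-step caller per chromosome: permutation-masked Spearman
#' matrix, bin signal, smoothed-minima segmentation with boundary
#' validation/refinement, and fusion. Chromosomes with fewer than 2w
#' surviving bins are skipped with a warning. Deterministic given the data
#' and \code{config$seed}.
#'
#' @param binned a [BinnedExpression-class].
#' @param samples sample ids (columns) of the group.
#' @param group group label.
#' @param config parameters from [dceConfig()].
#' @param chroms optional chromosome subset.
#' @return a [DCESet-class].
#' @export
callDCEs <- function(binned, samples, group = "group",
                     config = dceConfig(), chroms = NULL) {
    if (is.null(chroms))
        chroms <- unique(as.character(seqnames(rowRanges(binned))))
    pieces <- lapply(stats::setNames(chroms, chroms), function(ch)
        .callChrom(binned, samples, group, ch, config))
    .domainsToSet(pieces, binned, group, config)
}

#' Select the window size maximizing intra-domain correlation
#'
#' Runs the caller on a designated tuning chromosome for each candidate w and
#' returns the w whose resulting domains have the highest mean within-domain
#' masked correlation; ties go to the smallest w.
#'
#' @param binned a [BinnedExpression-class].
#' @param samples sample ids of the tuning group.
#' @param candidateWs integer vector of window sizes (>= 2 candidates unless
#'   one is supplied, which is returned unchanged).
#' @param chrom tuning chromosome (default: first).
#' @param config base configuration.
#' @return the selected window size.
#' @export
tuneWindow <- function(binned, samples, candidateWs, chrom = NULL,
                       config = dceConfig()) {
    candidateWs <- as.integer(candidateWs)
    if (length(candidateWs) == 1L) return(candidateWs)
    if (is.null(chrom))
        chrom <- as.character(seqnames(rowRanges(binned)))[1]
    scores <- vapply(candidateWs, function(w) {
        cfg <- config; cfg$w <- w
        p <- .callChrom(binned, samples, "tuning", chrom, cfg)
        if (is.null(p) || nrow(p$domains) == 0L) return(NA_real_)
        m <- maskedRho(p$mc)
        mean(unlist(lapply(seq_len(nrow(p$domains)), function(i) {
            b <- p$domains$start[i]:p$domains$end[i]
            upperTri(m[b, b, drop = FALSE])
        })))
    }, numeric(1))
    if (all(is.na(scores))) stop("no DCEs called for any candidate window")
    best <- which(scores == max(scores, na.rm = TRUE))
    min(candidateWs[best])
}

#' Genome-wide mean bin signal of a reference group
#'
#' Computes the bin signal on every chromosome for the designated reference
#' group and returns its genome-wide mean — the data-driven counterpart of
#' the fixed 0.25 signal threshold (the reference-genome average), for use
#' as \code{threshold} in [dceConfig()] when calling other groups.
#'
#' @param binned a [BinnedExpression-class].
#' @param samples sample ids of the reference group.
#' @param config parameters (w, nPerm, maskAlpha, seed) from [dceConfig()].
#' @param chroms optional chromosome subset.
#' @return mean bin-signal value across all surviving bins.
#' @export
referenceThreshold <- function(binned, samples, config = dceConfig(),
                               chroms = NULL) {
    if (is.null(chroms))
        chroms <- unique(as.character(seqnames(rowRanges(binned))))
    vals <- unlist(lapply(chroms, function(ch) {
        idx <- survivingBins(binned, samples, ch)
        if (length(idx) < 2L * config$w) return(NULL)
        m <- assay(binned, "meanExpr")[idx, samples, drop = FALSE]
        mc <- permutationMask(
            m, nPerm = config$nPerm, alpha = config$maskAlpha,
            seed = deriveSeed(config$seed,
                              match(ch, seqlevels(rowRanges(binned)))),
            sided = config$sided, chrom = ch, group = "reference",
            binIndexMap = idx)
        signalValues(binSignal(mc, config$w))
    }))
    if (length(vals) == 0L) stop("no chromosome has enough surviving bins")
    mean(vals)
}
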