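#' Simulation configuration
#'
#' Study-scale defaults: one chromosome of 150 10-kb bins, one 6-kb gene per
#' bin, 50 samples per group, negative-binomial counts with dispersion 0.1
#' (bulk RNA-seq scale overdispersion), log-normal baseline means
#' (median ~50 counts), latent-factor loading 1 inside planted blocks and
#' per-gene log-normal noise with sd 0.3.
#'
#' @param nChrom number of chromosomes.
#' @param nBins bins per chromosome.
#' @param binSize bin width in bp.
#' @param genesPerBin gene density.
#' @param geneLength gene length in bp (must fit its bin slot).
#' @param nSamples samples per group.
#' @param dispersion NB dispersion (size = 1/dispersion).
#' @param noiseSd sd of per-gene log-normal noise.
#' @param baseMeanLog,baseMeanSdLog log-normal parameters of baseline means.
#' @param lambda default latent loading of planted blocks.
#' @param seed seed for the genome-level draws (baseline means); sample-level
#'   draws take their own seed in [simulateCounts()].
#' @return named list.
#' @export
simConfig <- function(nChrom = 1, nBins = 150, binSize = 10000,
                      genesPerBin = 1, geneLength = 6000, nSamples = 50,
                      dispersion = 0.1, noiseSd = 0.3,
                      baseMeanLog = log(50), baseMeanSdLog = 1,
                      lambda = 1, seed = 1L) {
    stopifnot(nChrom >= 1, nBins >= 1, binSize > 0, genesPerBin >= 1,
              geneLength > 0, geneLength <= binSize / genesPerBin,
              nSamples >= 3, dispersion > 0, noiseSd >= 0, lambda >= 0)
    list(nChrom = nChrom, nBins = nBins, binSize = binSize,
         genesPerBin = genesPerBin, geneLength = geneLength,
         nSamples = nSamples, dispersion = dispersion, noiseSd = noiseSd,
         baseMeanLog = baseMeanLog, baseMeanSdLog = baseMeanSdLog,
         lambda = lambda, seed = as.integer(seed))
}

#' Simulate a gene annotation tiling the chromosomes
#'
#' Genes are laid deterministically, \code{genesPerBin} per bin, each inside
#' its bin slot (non-overlapping), all protein_coding. The per-gene bin index
#' is kept in metadata column \code{bin_id} (1-based within chromosome).
#'
#' @param cfg a [simConfig()] list.
#' @return annotation GRanges (gene_name, gene_type, bin_id).
#' @export
simulateAnnotation <- function(cfg) {
    slot <- cfg$binSize / cfg$genesPerBin
    grs <- lapply(seq_len(cfg$nChrom), function(ci) {
        ch <- paste0("chr", ci)
        bin <- rep(seq_len(cfg$nBins), each = cfg$genesPerBin)
        j <- rep(seq_len(cfg$genesPerBin), times = cfg$nBins)
        st <- (bin - 1L) * cfg$binSize + (j - 1L) * slot + 1L
        GRanges(ch, IRanges(start = st, width = cfg$geneLength),
                gene_name = sprintf("g_%s_%04d_%d", ch, bin, j),
                gene_type = "protein_coding", bin_id = bin)
    })
    suppressWarnings(do.call(c, grs))
}

#' Specify a planted co-expression block
#'
#' @param chrom chromosome name.
#' @param startBin,endBin 1-based inclusive bin range of the block.
#' @param lambda latent loading (co-expression strength; 0 disables).
#' @return one-row data.frame; rbind rows to form a block set.
#' @export
blockSpec <- function(chrom, startBin, endBin, lambda = 1) {
    stopifnot(endBin >= startBin, lambda >= 0)
    data.frame(chrom = chrom, startBin = as.integer(startBin),
               endBin = as.integer(endBin), lambda = lambda)
}

#' Simulate a grouped count matrix with planted co-expression blocks
#'
#' Baseline means are drawn once from \code{cfg$seed} (shared across groups
#' so that group differences come only from block geometry). For each sample
#' and active block a latent factor g ~ N(0,1) is drawn; gene i of the block
#' gets mean mu_i * exp(lambda * g + eps), eps ~ N(0, noiseSd), and counts
#' are negative binomial with the configured dispersion. Genes outside
#' blocks vary independently.
#'
#' @param genes annotation from [simulateAnnotation()].
#' @param cfg a [simConfig()] list.
#' @param blocks data.frame of [blockSpec()] rows (NULL for no structure).
#' @param nSamples number of samples (default \code{cfg$nSamples}).
#' @param seed sample-level seed.
#' @param samplePrefix sample-id prefix.
#' @return integer count matrix, genes x samples.
#' @export
simulateCounts <- function(genes, cfg, blocks = NULL,
                           nSamples = cfg$nSamples, seed = 1L,
                           samplePrefix = "s") {
    nG <- length(genes)
    set.seed(cfg$seed)
    baseLog <- stats::rnorm(nG, cfg$baseMeanLog, cfg$baseMeanSdLog)
    blockOf <- rep(0L, nG)
    if (!is.null(blocks) && nrow(blocks) > 0) {
        for (k in seq_len(nrow(blocks))) {
            hit <- as.character(seqnames(genes)) == blocks$chrom[k] &
                genes$bin_id >= blocks$startBin[k] &
                genes$bin_id <= blocks$endBin[k]
            blockOf[hit] <- k
        }
    }
    set.seed(seed)
    counts <- matrix(0L, nG, nSamples,
                     dimnames = list(as.character(genes$gene_name),
                                     paste0(samplePrefix, seq_len(nSamples))))
    nBlocks <- if (is.null(blocks)) 0L else nrow(blocks)
    for (s in seq_len(nSamples)) {
        g <- if (nBlocks > 0) stats::rnorm(nBlocks) else numeric(0)
        lam <- if (nBlocks > 0) blocks$lambda else numeric(0)
        eff <- ifelse(blockOf > 0, lam[pmax(blockOf, 1L)] * g[pmax(blockOf, 1L)], 0)
        eps <- stats::rnorm(nG, 0, cfg$noiseSd)
        mu <- exp(baseLog + eff + eps)
        counts[, s] <- stats::rnbinom(nG, mu = mu, size = 1 / cfg$dispersion)
    }
    counts
}

#' Destroy all positional structure by within-sample shuffling
#'
#' Permutes the gene rows independently inside each sample, preserving the
#' marginal count distributions while removing all co-expression blocks —
#' the global null for the caller.
#'
#' @param counts count matrix.
#' @param seed RNG seed.
#' @return shuffled matrix of the same shape and dimnames.
#' @export
shuffleWithinSamples <- function(counts, seed = 1L) {
    set.seed(seed)
    out <- counts
    n <- nrow(counts)
    for (j in seq_len(ncol(counts)))
        out[, j] <- counts[sample.int(n), j]
    dimnames(out) <- dimnames(counts)
    out
}

#' Scripted two-group scenarios for the seven dynamics categories
#'
#' Returns paired block specifications whose ideal DCE calls yield exactly
#' the named label, plus the focal region and the side(s) on which the label
#' is expected. Every scenario also carries a stable anchor block present in
#' both groups (bins 106-136) so each group always has at least one domain.
#'
#' @param name one of split, merge, emerge, deplete, expand, contract,
#'   intact.
#' @param cfg a [simConfig()] list (bin geometry).
#' @return list(name, refBlocks, queryBlocks, focalBins, expected,
#'   expectedSide).
#' @export
makeScenario <- function(name = c("split", "merge", "emerge", "deplete",
                                  "expand", "contract", "intact"),
                         cfg = simConfig()) {
    name <- match.arg(name)
    ch <- "chr1"
    lam <- cfg$lambda
    anchor <- blockSpec(ch, 106, 136, lam)
    full <- blockSpec(ch, 21, 61, lam)
    narrow <- blockSpec(ch, 31, 51, lam)
    fragA <- blockSpec(ch, 21, 35, lam)
    fragB <- blockSpec(ch, 46, 61, lam)
    sc <- switch(name,
        intact   = list(ref = full, query = full,
                        expected = "intact", side = "both"),
        split    = list(ref = full, query = rbind(fragA, fragB),
                        expected = "split", side = "ref"),
        merge    = list(ref = rbind(fragA, fragB), query = full,
                        expected = "merged", side = "query"),
        deplete  = list(ref = full, query = NULL,
                        expected = "depleted", side = "ref"),
        emerge   = list(ref = NULL, query = full,
                        expected = "emerged", side = "query"),
        expand   = list(ref = narrow, query = full,
                        expected = "expanded", side = "query"),
        contract = list(ref = full, query = narrow,
                        expected = "contracted", side = "query"))
    list(name = name,
         refBlocks = rbind(anchor, sc$ref),
         queryBlocks = rbind(anchor, sc$query),
         focalBins = c(21L, 61L),
         expected = sc$expected,
         expectedSide = sc$side)
}

#' Run one scenario end to end
#'
#' Simulates both groups, prepares (filter + RLE + length normalization over
#' the pooled samples), bins, calls DCEs per group, classifies the dynamics
#' and checks whether every called domain overlapping the focal region (on
#' the expected side) carries the expected label.
#'
#' @param name scenario name (see [makeScenario()]).
#' @param seed replicate seed (drives the count draws and the caller).
#' @param cfg simulation configuration.
#' @param config caller configuration; [dceConfig()] with the scenario-scale
#'   default of 200 permutation rounds.
#' @return list with \code{pass}, \code{labels} (focal labels seen),
#'   \code{report}, \code{refSet}, \code{querySet}, \code{binned},
#'   \code{scenario} and the group sample ids.
#' @export
runScenario <- function(name, seed = 1L, cfg = simConfig(),
                        config = dceConfig(nPerm = 200)) {
    sc <- makeScenario(name, cfg)
    genes <- simulateAnnotation(cfg)
    refCounts <- simulateCounts(genes, cfg, sc$refBlocks,
                                seed = deriveSeed(seed, 1), samplePrefix = "r")
    qCounts <- simulateCounts(genes, cfg, sc$queryBlocks,
                              seed = deriveSeed(seed, 2), samplePrefix = "q")
    counts <- cbind(refCounts, qCounts)
    prep <- prepareExpression(counts, genes)
    binned <- binExpression(prep$expr, prep$genes, binSize = cfg$binSize,
                            assignment = config$assignment)
    refSamples <- colnames(refCounts)
    qSamples <- colnames(qCounts)
    cfgRef <- config; cfgRef$seed <- deriveSeed(seed, 3)
    cfgQ <- config; cfgQ$seed <- deriveSeed(seed, 4)
    refSet <- callDCEs(binned, refSamples, "ref", cfgRef)
    querySet <- callDCEs(binned, qSamples, "query", cfgQ)
    report <- classifyDCEs(refSet, querySet,
                           intactJaccard = config$intactJaccard,
                           tol = cfg$binSize)
    focal <- GRanges("chr1", IRanges((sc$focalBins[1] - 1L) * cfg$binSize + 1L,
                                     sc$focalBins[2] * cfg$binSize))
    # labels of called domains overlapping the focal region, per side
    sideLabels <- function(df) {
        gr <- GRanges(df$chrom, IRanges(df$start, df$end))
        df$label[overlapsAny(gr, focal)]
    }
    labs <- switch(sc$expectedSide,
        ref = sideLabels(refLabels(report)),
        query = sideLabels(queryLabels(report)),
        both = c(sideLabels(refLabels(report)),
                 sideLabels(queryLabels(report))))
    pass <- length(labs) > 0 && all(labs == sc$expected)
    if (name == "deplete") {
        # additionally: nothing may be called at the focal locus in query
        qFoc <- sideLabels(queryLabels(report))
        pass <- pass && length(qFoc) == 0
    }
    list(pass = pass, labels = labs, report = report, refSet = refSet,
         querySet = querySet, binned = binned, scenario = sc,
         refSamples = refSamples, querySamples = qSamples, genes = prep$genes)
}

#' Randomly place non-overlapping co-expression blocks on a chromosome
#'
#' Draws \code{nBlocks} block widths uniformly from \code{widthRange} (bins)
#' and places them without overlap, at least \code{minGap} bins apart and
#' away from the chromosome ends, uniformly over admissible arrangements.
#'
#' @param cfg a [simConfig()] list.
#' @param nBlocks number of blocks.
#' @param widthRange c(min, max) block width in bins.
#' @param minGap minimal gap between blocks (and to the ends) in bins.
#' @param chrom chromosome name.
#' @param seed RNG seed.
#' @return data.frame of [blockSpec()] rows, sorted by start.
#' @export
randomBlocks <- function(cfg, nBlocks = 10, widthRange = c(8, 30),
                         minGap = 5, chrom = "chr1", seed = 1L) {
    set.seed(seed)
    widths <- sample(widthRange[1]:widthRange[2], nBlocks, replace = TRUE)
    padded <- widths + minGap
    free <- cfg$nBins - minGap - sum(padded)
    if (free < 0) stop("blocks do not fit the chromosome")
    picks <- sort(sample.int(free + nBlocks, nBlocks))
    gaps <- diff(c(0L, picks)) - 1L
    starts <- minGap + cumsum(gaps + c(0L, padded[-nBlocks])) + 1L
    do.call(rbind, lapply(seq_len(nBlocks), function(k)
        blockSpec(chrom, starts[k], starts[k] + widths[k] - 1L,
                  cfg$lambda)))
}

#' Fraction of planted block boundaries recovered by a segmentation
#'
#' A planted boundary (block start or end) counts as recovered when some
#' called domain boundary of the same kind lies within \code{tolBins} bins
#' of it.
#'
#' @param dce a [DCESet-class].
#' @param blocks planted blocks (data.frame of [blockSpec()] rows).
#' @param cfg the [simConfig()] used for the simulation.
#' @param tolBins tolerance in bins (default 1).
#' @return list with \code{rate}, \code{nRecovered} and \code{nBoundaries}.
#' @export
boundaryRecovery <- function(dce, blocks, cfg, tolBins = 1) {
    gr <- domains(dce)
    tol <- tolBins * cfg$binSize
    hits <- 0L
    for (k in seq_len(nrow(blocks))) {
        d <- gr[as.character(seqnames(gr)) == blocks$chrom[k]]
        bs <- (blocks$startBin[k] - 1) * cfg$binSize + 1
        be <- blocks$endBin[k] * cfg$binSize
        if (length(d) > 0) {
            if (min(abs(start(d) - bs)) <= tol) hits <- hits + 1L
            if (min(abs(end(d) - be)) <= tol) hits <- hits + 1L
        }
    }
    list(rate = hits / (2 * nrow(blocks)), nRecovered = hits,
         nBoundaries = 2L * nrow(blocks))
}
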