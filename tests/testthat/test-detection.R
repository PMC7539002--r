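test_that("binSignal matches the brute-force cross-window mean", {
    set.seed(13)
    for (rep in 1:5) {
        n <- sample(10:30, 1)
        m <- matrix(runif(n * n, -1, 1), n)
        m <- (m + t(m)) / 2
        diag(m) <- 1
        for (w in 2:3) {
            sig <- binSignal(mkMasked(m), w)
            expect_equal(signalValues(sig), oracleBinSignal(m, w),
                         tolerance = 1e-12)
        }
    }
})

test_that("binSignal shapes follow the block structure", {
    sig <- signalValues(binSignal(mkMasked(mkBlockMatrix(20, list(1:10), 1)), 3))
    expect_equal(sig[5], 1)                       # interior of the block
    expect_equal(sig[15], 0)                      # outside
    expect_true(all(diff(sig[7:13]) <= 1e-12))    # drops across the edge
    # fully masked matrix (identity: no off-diagonal correlation) -> zero signal
    expect_equal(signalValues(binSignal(mkMasked(diag(20)), 3)), rep(0, 20))
    # two adjacent perfect blocks: local minimum at the junction
    m2 <- mkBlockMatrix(24, list(1:12, 13:24), rho = 1)
    s2 <- signalValues(binSignal(mkMasked(m2), 3))
    expect_lt(s2[12], s2[8])
    expect_lt(s2[12], s2[16])
    expect_equal(s2[12], min(s2))
    expect_error(binSignal(mkMasked(mkBlockMatrix(5, list(1:2))), 3),
                 "fewer than 2w")
})

test_that("detectMinima finds qualifying minima and candidate segments", {
    # single basin below threshold flanked by high plateaus
    v <- c(rep(0.8, 10), 0.5, 0.1, 0.5, rep(0.8, 10))
    dm <- detectMinima(mkSignal(v), threshold = 0.25)
    expect_equal(dm$minima, 12L)
    expect_equal(nrow(dm$domains), 2)
    expect_equal(dm$domains$start, c(1L, 12L))
    expect_equal(dm$domains$end, c(12L, 23L))
    # signal everywhere below threshold: no domains
    low <- detectMinima(mkSignal(rep(0.1, 20) + sin(1:20) * 0.05), 0.25)
    expect_equal(nrow(low$domains), 0)
    # constant signal: no domains
    expect_equal(nrow(detectMinima(mkSignal(rep(0.5, 15)), 0.25)$domains), 0)
    # two basins: three candidate segments
    v2 <- c(rep(0.7, 5), 0.1, rep(0.7, 5), 0.1, rep(0.7, 5))
    dm2 <- detectMinima(mkSignal(v2), 0.25)
    expect_equal(dm2$minima, c(6L, 12L))
    expect_equal(nrow(dm2$domains), 3)
    # a minimum above the threshold does not qualify
    v3 <- c(rep(0.8, 5), 0.4, rep(0.8, 5))
    expect_equal(nrow(detectMinima(mkSignal(v3), 0.25)$domains), 1)
})

test_that("plateau minima take the leftmost position", {
    v <- c(0.8, 0.6, 0.1, 0.1, 0.1, 0.6, 0.8)
    expect_equal(detectMinima(mkSignal(v), 0.25)$minima, 3L)
})

test_that("evaluateBoundaries keeps perfect blocks and drops noise domains", {
    m <- mkBlockMatrix(30, list(11:20), rho = 0.9)
    mc <- mkMasked(m)
    out <- evaluateBoundaries(data.frame(start = 9L, end = 22L), mc, w = 3)
    expect_equal(nrow(out), 1)
    expect_equal(out$start, 11L)      # chopped to the true edge
    expect_equal(out$end, 20L)
    expect_lt(out$left_p, 0.05)
    expect_lt(out$right_p, 0.05)
    # a domain of zeros has no boundary support at any size
    outN <- evaluateBoundaries(data.frame(start = 2L, end = 8L),
                               mkMasked(diag(30) * 0 + diag(30)), w = 3)
    expect_equal(nrow(outN), 0)
})

test_that("a boundary one bin off needs exactly one chop", {
    m <- mkBlockMatrix(30, list(10:20), rho = 0.9)
    mc <- mkMasked(m)
    out <- evaluateBoundaries(data.frame(start = 9L, end = 20L), mc, w = 3)
    expect_equal(out$start, 10L)
    expect_equal(out$end, 20L)
})

test_that("rank-sum boundary statistics agree with the enumeration oracle", {
    set.seed(17)
    for (rep in 1:20) {
        x <- sample(c(0, 0, runif(3)), 3)
        y <- sample(c(rep(0, 7), runif(2)), 9)
        expect_equal(rankSumTest(x, y, "greater")$p.value,
                     oracleRankSumP(x, y, "greater"), tolerance = 1e-12)
    }
})

test_that("fuseDomains follows the two fusion criteria", {
    sigLow <- mkSignal(rep(0.1, 40))
    dom <- function(...) {
        d <- as.data.frame(matrix(c(...), ncol = 2, byrow = TRUE))
        names(d) <- c("start", "end")
        d$left_p <- 0.01; d$right_p <- 0.01
        d
    }
    # one low bin between two domains: fused
    f1 <- fuseDomains(dom(5, 10, 12, 18), sigLow)
    expect_equal(nrow(f1), 1)
    expect_equal(c(f1$start, f1$end), c(5, 18))
    # 1+1 intervening bins across three domains: one fused DCE
    f2 <- fuseDomains(dom(5, 10, 12, 18, 20, 26), sigLow)
    expect_equal(nrow(f2), 1)
    # four domains with 1-bin gaps: first three fuse, fourth stays
    f3 <- fuseDomains(dom(5, 10, 12, 18, 20, 26, 28, 34), sigLow)
    expect_equal(nrow(f3), 2)
    expect_equal(c(f3$start[1], f3$end[1]), c(5, 26))
    expect_equal(c(f3$start[2], f3$end[2]), c(28, 34))
    # a high-signal gap bin blocks fusion
    sigHigh <- mkSignal(c(rep(0.1, 10), 0.6, rep(0.1, 29)))
    f4 <- fuseDomains(dom(5, 10, 12, 18), sigHigh)
    expect_equal(nrow(f4), 2)
    # a 3-bin gap blocks fusion
    f5 <- fuseDomains(dom(5, 10, 14, 20), sigLow)
    expect_equal(nrow(f5), 2)
    # mean signal recomputed over the fused span
    expect_equal(f1$mean_signal, mean(rep(0.1, 14)))
})

test_that("fusion respects missing-bin runs in genomic space", {
    # surviving bins 1..20 map to grid bins with a 4-bin hole after bin 10
    idx <- c(1:10, 15:24)
    sig <- mkSignal(rep(0.1, 20), binIndexMap = idx)
    d <- data.frame(start = c(5L, 11L), end = c(10L, 16L),
                    left_p = 0.01, right_p = 0.01)
    out <- fuseDomains(d, sig)
    expect_equal(nrow(out), 2)   # adjacent on the surviving axis, 4 bins apart genomically
})

test_that("callDCEs recovers a planted block, deterministically", {
    fx <- mkScenarioBinned(nBins = 60, nSamples = 40, dispersion = 0.05,
                           blocks = blockSpec("chr1", 15, 40))
    cfg <- dceConfig(nPerm = 100, seed = 5)
    dce <- callDCEs(fx$binned, fx$samples, "g", cfg)
    expect_equal(length(dce), 1)
    gr <- domains(dce)
    expect_lte(abs(start(gr) - ((15 - 1) * 10000 + 1)), 10000)
    expect_lte(abs(end(gr) - 40 * 10000), 10000)
    expect_true(all(gr$left_p <= 0.05 | is.na(gr$left_p)))
    expect_true(all(gr$right_p <= 0.05 | is.na(gr$right_p)))
    # same config twice: identical output
    dce2 <- callDCEs(fx$binned, fx$samples, "g", cfg)
    expect_identical(domains(dce), domains(dce2))
    # domains never overlap (validity runs on construction)
    expect_true(validObject(dce))
})

test_that("gene lists attached to domains cover the domain span", {
    fx <- mkScenarioBinned(nBins = 60, nSamples = 40, dispersion = 0.05,
                           blocks = blockSpec("chr1", 15, 40))
    dce <- callDCEs(fx$binned, fx$samples, "g", dceConfig(nPerm = 100, seed = 5))
    gr <- domains(dce)
    genes <- fx$genes
    inSpan <- genes[overlapsAny(genes, gr)]
    expect_setequal(unlist(gr$genes), as.character(inSpan$gene_name))
})

test_that("tuneWindow picks a small window for narrow blocks and breaks ties low", {
    fx <- mkScenarioBinned(nBins = 60, nSamples = 40, dispersion = 0.05,
                           blocks = blockSpec("chr1", 20, 30))
    w <- tuneWindow(fx$binned, fx$samples, c(2, 3, 4), chrom = "chr1",
                    config = dceConfig(nPerm = 60, seed = 3))
    expect_true(w %in% 2:4)
    expect_equal(tuneWindow(fx$binned, fx$samples, 5L), 5L)
    # exact score ties resolve to the smallest window
    wTie <- tuneWindow(fx$binned, fx$samples, c(3L, 3L), chrom = "chr1",
                       config = dceConfig(nPerm = 60, seed = 3))
    expect_equal(wTie, 3L)
})

test_that("referenceThreshold averages the reference group's signal genome-wide", {
    fx <- mkScenarioBinned(nBins = 60, nSamples = 40, dispersion = 0.05,
                           blocks = blockSpec("chr1", 15, 40))
    cfg <- dceConfig(nPerm = 60, seed = 11)
    thr <- referenceThreshold(fx$binned, fx$samples, cfg)
    expect_true(is.finite(thr))
    # consistency with a manual per-chromosome computation
    idx <- survivingBins(fx$binned, fx$samples, "chr1")
    m <- SummarizedExperiment::assay(fx$binned)[idx, fx$samples]
    mc <- permutationMask(m, nPerm = 60, alpha = cfg$maskAlpha,
                          seed = dcescan:::deriveSeed(11, 1),
                          chrom = "chr1", binIndexMap = idx)
    expect_equal(thr, mean(signalValues(binSignal(mc, 3))))
})
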