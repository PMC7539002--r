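test_that("jaccardIndex handles identity, disjoint and partial overlap", {
    gr <- function(s, e) GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e))
    expect_equal(jaccardIndex(gr(1, 100), gr(1, 100)), 1)
    expect_equal(jaccardIndex(gr(1, 100), gr(200, 300)), 0)
    expect_equal(jaccardIndex(gr(1, 100), gr(51, 150)), 1 / 3)
    expect_error(jaccardIndex(gr(5, 4), gr(1, 100)), "zero-length")
    expect_error(jaccardIndex(
        gr(1, 10), GenomicRanges::GRanges("chr2", IRanges::IRanges(1, 10))),
        "same chromosome")
})

test_that("jaccardIndex matches brute-force basepair sets", {
    set.seed(23)
    for (rep in 1:30) {
        s1 <- sample.int(500, 1); e1 <- s1 + sample.int(300, 1)
        s2 <- sample.int(500, 1); e2 <- s2 + sample.int(300, 1)
        gr <- function(s, e) GenomicRanges::GRanges("chr1",
                                                    IRanges::IRanges(s, e))
        expect_equal(jaccardIndex(gr(s1, e1), gr(s2, e2)),
                     oracleJaccard(s1, e1, s2, e2), tolerance = 1e-12)
    }
})

test_that("bpDistance is a metric-like segmentation distance", {
    a <- mkDceGR("chr1", c(101, 501), c(300, 800))
    expect_equal(bpDistance(a, a, 1000), 0)
    b <- mkDceGR("chr1", c(151, 501), c(350, 700))
    expect_equal(bpDistance(a, b, 1000), bpDistance(b, a, 1000))
    d <- bpDistance(a, b, 1000)
    expect_gt(d, 0); expect_lt(d, 1)
    expect_error(bpDistance(a, mkDceGR("chr1", 1, 2000), 1000), "exceed")
})

test_that("bpDistance matches the per-basepair oracle on random partitions", {
    set.seed(29)
    for (rep in 1:30) {
        L <- 400
        mk <- function() {
            k <- sample(0:3, 1)
            if (k == 0) return(mkDceGR("chr1", integer(0), integer(0)))
            pos <- sort(sample.int(L - 1, 2 * k))
            mkDceGR("chr1", pos[seq(1, 2 * k, 2)], pos[seq(2, 2 * k, 2)])
        }
        a <- mk(); b <- mk()
        expect_equal(
            bpDistance(a, b, L),
            oracleBpDist(data.frame(start = start(a), end = end(a)),
                         data.frame(start = start(b), end = end(b)), L),
            tolerance = 1e-12)
    }
})

test_that("classifyDCEs reproduces the canonical category examples", {
    ref <- mkDceGR("chr1", 1, 1000)
    # split: one reference over two query fragments
    q <- mkDceGR("chr1", c(1, 601), c(400, 1000))
    rep1 <- classifyDCEs(ref, q, tol = 10)
    expect_equal(refLabels(rep1)$label, "split")
    expect_equal(queryLabels(rep1)$label, c("split", "split"))
    # merged is the mirror image
    rep2 <- classifyDCEs(q, ref, tol = 10)
    expect_equal(refLabels(rep2)$label, c("merged", "merged"))
    expect_equal(queryLabels(rep2)$label, "merged")
    # depleted / emerged
    far <- mkDceGR("chr1", 5001, 6000)
    rep3 <- classifyDCEs(ref, far)
    expect_equal(refLabels(rep3)$label, "depleted")
    expect_equal(queryLabels(rep3)$label, "emerged")
    # intact at Jaccard 1
    rep4 <- classifyDCEs(ref, mkDceGR("chr1", 1, 1000))
    expect_equal(refLabels(rep4)$label, "intact")
    # expanded / contracted
    wide <- mkDceGR("chr1", 1, 2000)
    expect_equal(refLabels(classifyDCEs(ref, wide))$label, "expanded")
    expect_equal(refLabels(classifyDCEs(wide, ref))$label, "contracted")
    # near-identical above the cutoff stays intact
    expect_equal(refLabels(classifyDCEs(ref, mkDceGR("chr1", 1, 1100),
                                        intactJaccard = 0.8))$label,
                 "intact")
    expect_error(classifyDCEs(mkDceGR("chr1", c(1, 50), c(100, 150)), ref),
                 "must not overlap")
})

test_that("classification is exhaustive, exclusive and swap-symmetric", {
    set.seed(37)
    swapMap <- c(intact = "intact", depleted = "emerged",
                 emerged = "depleted", split = "merged", merged = "split",
                 expanded = "contracted", contracted = "expanded")
    mk <- function() {
        k <- sample(1:6, 1)
        pos <- sort(sample(seq(1, 5000, 7), 2 * k))
        w <- which(pos[seq(2, 2 * k, 2)] - pos[seq(1, 2 * k, 2)] > 0)
        mkDceGR("chr1", pos[seq(1, 2 * k, 2)][w], pos[seq(2, 2 * k, 2)][w])
    }
    for (rep in 1:25) {
        a <- mk(); b <- mk()
        if (length(a) == 0 || length(b) == 0) next
        fwd <- classifyDCEs(a, b, tol = 10)
        bwd <- classifyDCEs(b, a, tol = 10)
        expect_false(anyNA(refLabels(fwd)$label))
        expect_false(anyNA(queryLabels(fwd)$label))
        expect_true(all(refLabels(fwd)$label %in% names(swapMap)))
        expect_equal(unname(swapMap[refLabels(fwd)$label]),
                     queryLabels(bwd)$label)
        expect_equal(unname(swapMap[queryLabels(fwd)$label]),
                     refLabels(bwd)$label)
        cnt <- dynamicsCounts(fwd)
        expect_equal(sum(cnt$ratio), 1)
    }
})

test_that("findDisruptors applies the three defining conditions", {
    ref <- mkDceGR("chr1", 1, 1000)
    query <- mkDceGR("chr1", c(1, 601), c(400, 1000))
    genes <- mkGenes(c("inGap", "inFragment", "straddler", "outside"),
                     "chr1",
                     c(451, 101, 351, 1500),
                     c(550, 200, 450, 1600))
    d <- findDisruptors(ref, query, genes)
    expect_equal(d$genes, "inGap")
    expect_equal(length(d$fragments), 2)
    # gap is the locus between the fragments
    expect_equal(start(d$gaps), 401)
    expect_equal(end(d$gaps), 600)
    expect_error(findDisruptors(ref, mkDceGR("chr1", 1, 400), genes),
                 "not split")
    # no genes in the gap -> empty set
    d2 <- findDisruptors(ref, query, genes[genes$gene_name != "inGap"])
    expect_equal(length(d2$genes), 0)
})

test_that("disruptorTable collects split events across a report", {
    ref <- mkDceGR("chr1", c(1, 3001), c(1000, 4000))
    query <- mkDceGR("chr1", c(1, 601, 3001), c(400, 1000, 4000))
    genes <- mkGenes(c("dis1", "keeper"), "chr1", c(451, 3100), c(550, 3200))
    rep <- classifyDCEs(ref, query, tol = 10)
    tab <- disruptorTable(rep, ref, query, genes)
    expect_equal(tab$gene, "dis1")
    expect_equal(tab$ref_dce, refLabels(rep)$dce_id[1])
})

test_that("coverageStats computes eligible-bin fractions", {
    el <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(seq(1, by = 100, length.out = 100), width = 100))
    one <- mkDceGR("chr1", 1, 1000)     # covers 10 of 100 bins
    expect_equal(coverageStats(one, el)$genomeFraction, 0.1)
    none <- mkDceGR("chr1", integer(0), integer(0))
    expect_equal(coverageStats(none, el)$genomeFraction, 0)
    el2 <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(seq(1, by = 100, length.out = 200), width = 100))
    two <- mkDceGR("chr1", c(1, 10001), c(500, 11500))   # 5 + 15 bins
    cs <- coverageStats(two, el2)
    expect_equal(cs$genomeFraction, 0.1)
    expect_equal(cs$nDce, 2)
})
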