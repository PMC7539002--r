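test_that("filterGenes removes excluded biotypes and cross-chromosome duplicates", {
    gr <- mkGenes(c("A", "B", "C", "C", "D", "D"),
                  c("chr1", "chr1", "chr1", "chr2", "chr1", "chr1"),
                  c(1, 1000, 2000, 10, 3000, 3500),
                  c(500, 1500, 2500, 400, 3400, 3900),
                  types = c("protein_coding", "pseudogene", "protein_coding",
                            "protein_coding", "protein_coding",
                            "protein_coding"))
    out <- filterGenes(gr)
    # B: excluded biotype; C: two chromosomes; D: same-chrom duplicate merged
    expect_setequal(out$gene_name, c("A", "D"))
    expect_equal(start(out[out$gene_name == "D"]), 3000)
    expect_equal(end(out[out$gene_name == "D"]), 3900)
    # biotype matching is separator-insensitive
    gr2 <- mkGenes(c("E", "F"), "chr1", c(1, 100), c(50, 200),
                   types = c("Mt-tRNA", "processed transcript"))
    expect_error(filterGenes(gr2), "no genes survive")
})

test_that("filterGenes is the identity on clean tables and is idempotent", {
    gr <- mkGenes(c("A", "B"), "chr1", c(1, 1000), c(500, 1500))
    once <- filterGenes(gr)
    expect_equal(as.character(once$gene_name), c("A", "B"))
    expect_identical(filterGenes(once), once)
})

test_that("filterGenes treats missing gene_type as excluded, with a warning", {
    gr <- mkGenes(c("A", "B"), "chr1", c(1, 1000), c(500, 1500),
                  types = c("protein_coding", NA))
    expect_warning(out <- filterGenes(gr), "missing gene_type")
    expect_equal(as.character(out$gene_name), "A")
})

test_that("dropZeroGenes keeps exactly the genes with some signal", {
    m <- rbind(a = c(0, 0, 0), b = c(0, 1, 0), c = c(5, 2, 1))
    out <- dropZeroGenes(m)
    expect_equal(rownames(out), c("b", "c"))
    expect_identical(dropZeroGenes(out), out)   # identity when all non-zero
    one <- matrix(c(0, 3), 1, dimnames = list("g", NULL))
    expect_equal(rownames(dropZeroGenes(one)), "g")
})

test_that("rleNormalize matches the hand-computed median-of-ratios toy", {
    # 3-gene toy, sample2 = 2 x sample1: geometric means sqrt(2)*c1, so the
    # ratio medians are 1/sqrt(2) and sqrt(2)*... computed by hand below.
    m <- cbind(s1 = c(10, 20, 40), s2 = c(20, 40, 80))
    rownames(m) <- paste0("g", 1:3)
    geo <- sqrt(m[, 1] * m[, 2])
    sfExp <- c(median(m[, 1] / geo), median(m[, 2] / geo))
    out <- rleNormalize(m)
    expect_equal(unname(attr(out, "sizeFactors")), unname(sfExp))
    # scaled samples normalize to identical columns
    expect_equal(unname(out[, 1]), unname(out[, 2]))
})

test_that("rleNormalize handles symmetric, single-sample and degenerate inputs", {
    m <- cbind(s1 = c(3, 9, 27), s2 = c(3, 9, 27))
    rownames(m) <- paste0("g", 1:3)
    out <- rleNormalize(m)
    sf <- attr(out, "sizeFactors")
    expect_equal(sf[[1]], sf[[2]])
    one <- m[, 1, drop = FALSE]
    expect_equal(unname(attr(rleNormalize(one), "sizeFactors")), 1)
    expect_equal(rleNormalize(one), one, ignore_attr = TRUE)
    bad <- cbind(s1 = c(1, 0), s2 = c(0, 1))
    expect_error(rleNormalize(bad), "RLE reference undefined")
})

test_that("rleNormalize absorbs per-sample scaling up to one global constant", {
    # median-of-ratios uses the cross-sample geometric mean as reference, so
    # scaling one column by c rescales the whole normalized matrix by
    # exactly c^(1/S) and changes nothing else — sample ratios and all
    # downstream rank correlations are untouched.
    set.seed(1)
    m <- matrix(rpois(60, 30) + 1, 20, 3,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:3)))
    base <- rleNormalize(m)
    for (cc in c(0.5, 3)) {
        m2 <- m
        m2[, 2] <- m[, 2] * cc
        out <- rleNormalize(m2)
        ratio <- out / base
        expect_equal(unname(ratio), matrix(cc^(1 / 3), 20, 3),
                     tolerance = 1e-12, ignore_attr = TRUE)
    }
})

test_that("rleNormalize agrees with the DESeq2 median-of-ratios estimator", {
    set.seed(2)
    m <- matrix(rnbinom(200, mu = 50, size = 5) + 1, 40, 5,
                dimnames = list(paste0("g", 1:40), paste0("s", 1:5)))
    sf <- attr(rleNormalize(m), "sizeFactors")
    ref <- DESeq2::estimateSizeFactorsForMatrix(m)
    expect_equal(unname(sf), unname(ref), tolerance = 1e-10)
})

test_that("lengthNormalize rescales by gene length in the stated units", {
    genes <- mkGenes(c("a", "b"), "chr1", c(1, 5001), c(500, 7000))
    m <- matrix(c(4, 8), 2, 1, dimnames = list(c("a", "b"), "s1"))
    out <- lengthNormalize(m, genes, scale = 1000)
    expect_equal(unname(out[, 1]), c(4 * 1000 / 500, 8 * 1000 / 2000))
    # 1 kb gene at scale 1000 is unchanged
    g1k <- mkGenes("a", "chr1", 1, 1000)
    m1 <- matrix(6, 1, 1, dimnames = list("a", "s1"))
    expect_equal(unname(lengthNormalize(m1, g1k)[, 1]), 6)
    # doubling the annotated length halves the value
    g2k <- mkGenes("a", "chr1", 1, 2000)
    expect_equal(unname(lengthNormalize(m1, g2k)[, 1]), 3)
    expect_error(lengthNormalize(m, genes[1], scale = 1000), "no annotated length")
})

test_that("stratifySamples maps SLEDAI to strata and partitions every sample", {
    meta <- data.frame(sample_id = c("p0", "p2", "p3", "p8", "p9", "h"),
                       sledai = c(0, 2, 3, 8, 9, NA),
                       group = c(NA, NA, NA, NA, NA, "healthy"))
    out <- stratifySamples(meta)
    expect_equal(as.character(out$group),
                 c("low", "low", "intermediate", "intermediate", "high",
                   "healthy"))
    expect_false(anyNA(out$group))
    expect_error(stratifySamples(data.frame(sample_id = "x", sledai = -1)),
                 "negative")
    expect_error(stratifySamples(data.frame(sample_id = "x",
                                            sledai = NA_real_)),
                 "SLEDAI required")
    expect_error(stratifySamples(data.frame(sample_id = c("x", "y"),
                                            sledai = c(1, 9),
                                            group = c("low", "low"))),
                 "inconsistent")
})

test_that("prepareExpression composes the fixed filter/normalize order", {
    genes <- mkGenes(c("A", "B", "Z"), "chr1", c(1, 2001, 4001),
                     c(1000, 3000, 5000),
                     types = c("protein_coding", "protein_coding",
                               "pseudogene"))
    counts <- rbind(A = c(10, 20), B = c(0, 0), Z = c(5, 5),
                    unknown = c(9, 9))
    colnames(counts) <- c("s1", "s2")
    expect_message(prep <- prepareExpression(counts, genes), "dropped")
    # Z excluded by biotype, B all-zero, unknown not annotated
    expect_equal(rownames(prep$expr), "A")
    expect_equal(as.character(prep$genes$gene_name), "A")
    expect_true(all(prep$sizeFactors > 0))
})
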