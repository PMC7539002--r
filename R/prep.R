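#' Biotypes excluded from the analysis by default
#'
#' The fourteen annotation biotypes removed before normalization:
#' pseudogenes and pseudogene sub-classes, processed transcripts, antisense
#' and sense-overlapping transcripts, non-coding entries and mitochondrial
#' tRNA/rRNA. Matching is separator-insensitive (spaces/hyphens treated as
#' underscores).
#'
#' @return character vector of biotype names.
#' @export
dceExcludedBiotypes <- function() {
    c("pseudogene", "processed_transcript", "polymorphic_pseudogene",
      "antisense", "sense_intronic", "sense_overlapping",
      "IG_V_pseudogene", "IG_C_pseudogene", "TR_V_pseudogene",
      "TR_J_pseudogene", "IG_J_pseudogene", "non_coding",
      "Mt_tRNA", "Mt_rRNA")
}

#' Filter a gene annotation table
#'
#' Removes genes of excluded biotypes (and genes with missing biotype, which
#' are treated conservatively as excluded, with a warning reporting how many),
#' drops genes whose \code{gene_name} occurs on more than one chromosome, and
#' collapses same-chromosome duplicate entries to their span union so that
#' \code{gene_name} is unique afterwards. Relative gene order is preserved.
#'
#' @param genes a \link[GenomicRanges]{GRanges} with metadata columns
#'   \code{gene_name} and \code{gene_type}.
#' @param excludedTypes biotypes to drop; see [dceExcludedBiotypes()].
#' @return the filtered GRanges.
#' @examples
#' gr <- GenomicRanges::GRanges(c("chr1", "chr1"),
#'         IRanges::IRanges(c(1, 500), c(400, 900)),
#'         gene_name = c("A", "B"),
#'         gene_type = c("protein_coding", "pseudogene"))
#' filterGenes(gr)
#' @export
filterGenes <- function(genes, excludedTypes = dceExcludedBiotypes()) {
    if (length(genes) == 0L) stop("gene table is empty")
    if (!all(c("gene_name", "gene_type") %in% colnames(mcols(genes))))
        stop("'genes' must carry gene_name and gene_type metadata columns")
    type <- normalizeBiotype(as.character(genes$gene_type))
    missing <- is.na(type) | type == ""
    if (any(missing))
        warning(sum(missing), " genes with missing gene_type were excluded")
    keep <- !missing & !(type %in% normalizeBiotype(excludedTypes))
    genes <- genes[keep]
    if (length(genes) == 0L) stop("no genes survive filtering")

    nm <- as.character(genes$gene_name)
    chr <- as.character(seqnames(genes))
    # names seen on >1 chromosome are dropped outright
    nchrom <- rowSums(table(nm, chr) > 0)
    multi <- names(nchrom)[nchrom > 1]
    genes <- genes[!nm %in% multi]
    if (length(genes) == 0L) stop("no genes survive filtering")

    # same-chromosome duplicates: merge to the span union, keep first slot
    nm <- as.character(genes$gene_name)
    if (anyDuplicated(nm)) {
        first <- !duplicated(nm)
        st <- tapply(start(genes), nm, min)[nm[first]]
        en <- tapply(end(genes), nm, max)[nm[first]]
        genes <- genes[first]
        ranges(genes) <- IRanges(start = as.integer(st),
                                 end = as.integer(en))
    }
    genes
}

#' Drop genes with all-zero counts
#'
#' @param counts integer matrix, genes x samples, rownames = gene names.
#' @return the matrix restricted to genes with at least one non-zero count.
#' @export
dropZeroGenes <- function(counts) {
    counts <- as.matrix(counts)
    if (any(counts < 0)) stop("counts must be non-negative")
    counts[rowSums(counts != 0) > 0L, , drop = FALSE]
}

#' Relative log expression (median-of-ratios) normalization
#'
#' Per-sample size factor = median, over genes with a positive geometric mean
#' across samples, of count / geometric mean; normalized value = count / size
#' factor. Equivalent to the median-of-ratios estimator used for library-size
#' correction of RNA-seq counts.
#'
#' @param counts non-negative matrix, genes x samples.
#' @return the normalized matrix, with the per-sample factors attached as
#'   attribute \code{"sizeFactors"}.
#' @examples
#' m <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
#' rownames(m) <- paste0("g", 1:3)
#' sf <- attr(rleNormalize(m), "sizeFactors")
#' @export
rleNormalize <- function(counts) {
    counts <- as.matrix(counts)
    if (any(counts < 0)) stop("counts must be non-negative")
    logGeo <- rowMeans(log(counts))
    ref <- is.finite(logGeo)             # genes positive in all samples
    if (!any(ref)) stop("RLE reference undefined: no gene is expressed in ",
                        "all samples")
    sf <- apply(counts[ref, , drop = FALSE], 2, function(cnt)
        exp(stats::median(log(cnt) - logGeo[ref])))
    if (any(!is.finite(sf) | sf <= 0))
        stop("RLE reference undefined: non-positive size factor")
    out <- sweep(counts, 2, sf, "/")
    attr(out, "sizeFactors") <- sf
    out
}

#' Gene lengths for length normalization
#'
#' @param genes GRanges annotation (gene-level spans).
#' @param mode "span" uses the annotated gene-body span; "exon_union"
#'   requires \code{exons}, a \link[GenomicRanges]{GRangesList} of exons named
#'   by gene, and uses the width of the reduced exon union.
#' @param exons optional GRangesList for \code{mode = "exon_union"}.
#' @return named numeric vector of lengths in bp.
#' @export
geneLengths <- function(genes, mode = c("span", "exon_union"), exons = NULL) {
    mode <- match.arg(mode)
    if (mode == "span") {
        stats::setNames(width(genes), as.character(genes$gene_name))
    } else {
        if (is.null(exons))
            stop("mode 'exon_union' requires exon features")
        stats::setNames(vapply(reduce(exons), function(g) sum(width(g)),
                               numeric(1)), names(exons))
    }
}

#' Normalize expression for gene length
#'
#' Divides each gene's values by its length, rescaled so that
#' \code{scale = 1000} yields per-kilobase units. Length normalization is a
#' pure per-gene rescaling and does not affect rank correlations downstream.
#'
#' @param norm matrix from [rleNormalize()] (genes x samples).
#' @param genes GRanges annotation covering every matrix gene.
#' @param scale length unit in bp (default 1000, i.e. per kb).
#' @param lengths optional precomputed named length vector (overrides
#'   \code{genes}); see [geneLengths()].
#' @return matrix of the same shape.
#' @export
lengthNormalize <- function(norm, genes, scale = 1000, lengths = NULL) {
    .assertScalarNumber(scale, "scale")
    if (is.null(lengths)) lengths <- geneLengths(genes)
    miss <- setdiff(rownames(norm), names(lengths))
    if (length(miss) > 0)
        stop("no annotated length for genes: ",
             paste(utils::head(miss, 10), collapse = ", "),
             if (length(miss) > 10) " ...")
    out <- norm * (scale / lengths[rownames(norm)])
    attr(out, "sizeFactors") <- attr(norm, "sizeFactors")
    out
}

#' Stratify samples by disease-activity score
#'
#' Patients are assigned to activity strata by their SLEDAI score: low when
#' SLEDAI <= 2, intermediate for 3-8, high above 8. Samples already labelled
#' "healthy" pass through unchanged (their score may be missing). When both a
#' group and a score are present they must agree.
#'
#' @param meta data.frame with columns \code{sample_id} and \code{sledai}
#'   and/or \code{group}.
#' @return the data.frame with a validated \code{group} column, one of
#'   healthy / low / intermediate / high.
#' @examples
#' stratifySamples(data.frame(sample_id = c("p1", "p2", "h1"),
#'                            sledai = c(0, 9, NA),
#'                            group = c(NA, NA, "healthy")))
#' @export
stratifySamples <- function(meta) {
    meta <- as.data.frame(meta)
    if (!"sample_id" %in% names(meta)) stop("missing column 'sample_id'")
    if (anyDuplicated(meta$sample_id)) stop("duplicated sample_id")
    if (!"group" %in% names(meta)) meta$group <- NA_character_
    meta$group <- as.character(meta$group)
    healthy <- !is.na(meta$group) & meta$group == "healthy"
    if (!"sledai" %in% names(meta)) meta$sledai <- NA_real_
    s <- meta$sledai
    if (any(!is.na(s) & s < 0)) stop("negative SLEDAI score")
    if (any(!is.na(s) & s != floor(s))) stop("SLEDAI must be integer-valued")
    if (any(!healthy & is.na(s)))
        stop("SLEDAI required for all non-healthy samples")
    derived <- ifelse(healthy, "healthy",
               ifelse(s <= 2, "low",
               ifelse(s <= 8, "intermediate", "high")))
    given <- !is.na(meta$group) & !healthy
    if (any(given & meta$group != derived[given]))
        stop("given group inconsistent with SLEDAI for: ",
             paste(meta$sample_id[given & meta$group != derived], collapse = ", "))
    meta$group <- factor(derived,
                         levels = c("healthy", "low", "intermediate", "high"))
    meta
}

#' Filter, normalize and annotate a raw count matrix
#'
#' Applies the fixed preparation order: biotype filter, duplicate filter,
#' restriction of the count matrix to annotated genes, removal of all-zero
#' genes, RLE normalization (jointly over all samples so groups stay
#' comparable, unless \code{perGroup} sample subsets are given), and gene
#' length normalization.
#'
#' @param counts raw count matrix (genes x samples).
#' @param genes annotation GRanges (gene_name, gene_type).
#' @param excludedTypes see [filterGenes()].
#' @param lengthMode "span" or "exon_union" (see [geneLengths()]).
#' @param exons exon GRangesList for \code{lengthMode = "exon_union"}.
#' @param scale length unit in bp passed to [lengthNormalize()].
#' @param groups optional named list of sample-id vectors; when given, RLE is
#'   run within each group separately instead of jointly.
#' @return list with \code{expr} (normalized matrix), \code{genes} (filtered
#'   annotation restricted to matrix genes) and \code{sizeFactors}.
#' @export
prepareExpression <- function(counts, genes,
                              excludedTypes = dceExcludedBiotypes(),
                              lengthMode = c("span", "exon_union"),
                              exons = NULL, scale = 1000, groups = NULL) {
    lengthMode <- match.arg(lengthMode)
    counts <- as.matrix(counts)
    genes <- filterGenes(genes, excludedTypes)
    keep <- rownames(counts) %in% as.character(genes$gene_name)
    if (!all(keep))
        message(sum(!keep), " count-matrix genes absent from the filtered ",
                "annotation were dropped")
    counts <- counts[keep, , drop = FALSE]
    counts <- dropZeroGenes(counts)
    if (nrow(counts) == 0L) stop("no genes survive filtering")
    if (is.null(groups)) {
        norm <- rleNormalize(counts)
        sf <- attr(norm, "sizeFactors")
    } else {
        norm <- counts * NA_real_
        sf <- stats::setNames(numeric(ncol(counts)), colnames(counts))
        for (g in names(groups)) {
            nb <- rleNormalize(counts[, groups[[g]], drop = FALSE])
            norm[, groups[[g]]] <- nb
            sf[groups[[g]]] <- attr(nb, "sizeFactors")
        }
    }
    lens <- geneLengths(genes, lengthMode, exons)
    expr <- lengthNormalize(norm, genes, scale = scale, lengths = lens)
    genes <- genes[match(rownames(expr), as.character(genes$gene_name))]
    list(expr = expr, genes = genes, sizeFactors = sf)
}
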