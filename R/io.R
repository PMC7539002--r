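#' Read a gene-level annotation from GTF
#'
#' Imports a GTF (via rtracklayer), keeps gene-level features when a
#' \code{type} column is present, and returns a GRanges with the
#' \code{gene_name} and \code{gene_type} metadata columns the rest of the
#' pipeline expects. GTF coordinates (1-based inclusive) map directly onto
#' GRanges.
#'
#' @param path GTF file.
#' @return GRanges with gene_name and gene_type.
#' @export
readGeneAnnotation <- function(path) {
    gr <- rtracklayer::import(path, format = "gtf")
    mc <- mcols(gr)
    if ("type" %in% colnames(mc) && any(mc$type == "gene"))
        gr <- gr[mc$type == "gene"]
    mc <- mcols(gr)
    if (!"gene_name" %in% colnames(mc)) {
        if ("gene_id" %in% colnames(mc)) gr$gene_name <- gr$gene_id
        else stop("GTF lacks gene_name attribute")
    }
    if (!"gene_type" %in% colnames(mc)) {
        if ("gene_biotype" %in% colnames(mc)) gr$gene_type <- gr$gene_biotype
        else gr$gene_type <- NA_character_
    }
    mcols(gr) <- mcols(gr)[, c("gene_name", "gene_type")]
    gr
}

#' Read a count matrix from TSV
#'
#' First column = gene name, remaining columns = one per sample.
#'
#' @param path TSV file.
#' @return integer matrix with gene rownames.
#' @export
readCounts <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    if (any(is.na(m))) stop("count matrix contains missing values")
    if (any(m < 0)) stop("count matrix contains negative values")
    storage.mode(m) <- "numeric"
    m
}

#' Read sample metadata from TSV
#'
#' Expects columns \code{sample_id} plus \code{group} and/or \code{sledai};
#' runs [stratifySamples()] on the result.
#'
#' @param path TSV file.
#' @return data.frame with a validated \code{group} column.
#' @export
readSampleMetadata <- function(path) {
    stratifySamples(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Read gene sets from a two-column TSV (set_name, gene_name)
#'
#' @param path TSV file.
#' @return named list of character vectors.
#' @export
readGeneSets <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("gene-set table needs columns set_name, gene_name")
    split(as.character(df[[2]]), df[[1]])
}

#' Read an interval track (BED4: labels in the name field)
#'
#' @param path BED file.
#' @return GRanges with a \code{label} metadata column.
#' @export
readTrack <- function(path) {
    gr <- rtracklayer::import(path, format = "bed")
    gr$label <- if (!is.null(gr$name)) gr$name else "track"
    gr
}

#' Read enhancer-promoter links from TSV
#'
#' Columns: gene, chrom, promoter_pos, enh_start, enh_end and optionally
#' cell_type. Coordinates are 1-based.
#'
#' @param path TSV file.
#' @return data.frame of links.
#' @export
readEpLinks <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene", "chrom", "promoter_pos", "enh_start", "enh_end")
    if (!all(need %in% names(df)))
        stop("EP link table needs columns: ", paste(need, collapse = ", "))
    if (!"cell_type" %in% names(df)) df$cell_type <- NA_character_
    df
}

#' Export a DCESet as BED6+
#'
#' Writes chrom, start, end, name (dce_id), score (1000 x mean signal,
#' clamped to [0, 1000]) and strand "." with rtracklayer, which performs the
#' 0-based half-open conversion.
#'
#' @param dce a [DCESet-class].
#' @param path output BED file.
#' @export
writeDceBed <- function(dce, path) {
    gr <- domains(dce)
    out <- granges(gr)
    out$name <- gr$dce_id
    out$score <- pmin(pmax(round(1000 * gr$mean_signal), 0), 1000)
    rtracklayer::export(out, path, format = "bed")
    invisible(path)
}

#' Read a DCE BED file back into a DCESet
#'
#' Boundary p-values and bin indices are not stored in BED and come back NA.
#'
#' @param path BED file written by [writeDceBed()].
#' @param group group label to attach.
#' @return a [DCESet-class].
#' @export
readDceBed <- function(path, group = "unknown") {
    gr <- rtracklayer::import(path, format = "bed")
    mcols(gr) <- DataFrame(
        dce_id = if (!is.null(gr$name)) gr$name
                 else if (length(gr)) paste0("dce_", seq_len(length(gr)))
                 else character(0),
        start_bin = NA_integer_, end_bin = NA_integer_,
        mean_signal = if (!is.null(gr$score)) gr$score / 1000 else NA_real_,
        left_p = NA_real_, right_p = NA_real_,
        genes = CharacterList(vector("list", length(gr))))
    new("DCESet", domains = sort(gr), group = group, params = list())
}

#' Write the per-DCE table (coordinates, boundary p-values, gene lists)
#'
#' @param dce a [DCESet-class].
#' @param path output TSV.
#' @export
writeDceTable <- function(dce, path) {
    gr <- domains(dce)
    df <- data.frame(
        dce_id = gr$dce_id, chrom = as.character(seqnames(gr)),
        start = start(gr), end = end(gr),
        start_bin = gr$start_bin, end_bin = gr$end_bin,
        mean_signal = gr$mean_signal,
        left_p = gr$left_p, right_p = gr$right_p,
        genes = vapply(gr$genes, paste, character(1), collapse = ","))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write a binned expression matrix and its bin-to-gene map as TSV
#'
#' @param binned a [BinnedExpression-class].
#' @param path output TSV (bin coordinates + one column per sample). The gene
#'   map is written alongside with suffix \code{.genes.tsv}.
#' @export
writeBinnedExpression <- function(binned, path) {
    gr <- rowRanges(binned)
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     bin_start = start(gr), bin_end = end(gr),
                     assay(binned, "meanExpr"), check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    gm <- data.frame(chrom = as.character(seqnames(gr)),
                     bin_start = start(gr), bin_end = end(gr),
                     genes = vapply(rowData(binned)$geneList, paste,
                                    character(1), collapse = ","))
    utils::write.table(gm, paste0(path, ".genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Export the bin grid as BED
#'
#' @param binned a [BinnedExpression-class] (or a bin-grid GRanges).
#' @param path output BED file.
#' @export
writeGridBed <- function(binned, path) {
    gr <- if (is(binned, "BinnedExpression")) rowRanges(binned) else binned
    rtracklayer::export(granges(gr), path, format = "bed")
    invisible(path)
}

#' Write / read a masked correlation matrix as TSV triplets
#'
#' Only non-zero masked coefficients are stored (bin_i, bin_j, masked_rho on
#' the surviving-bin axis, i <= j), plus a header block with the parameters
#' and the bin index map, sufficient to rebuild the masked matrix.
#'
#' @param mc a [MaskedCorrelation-class].
#' @param path output TSV.
#' @export
writeMaskedCorrelation <- function(mc, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
        paste0("# chrom=", mc@chrom, " group=", mc@group,
               " nPerm=", mc@nPerm, " alpha=", mc@alpha,
               " seed=", mc@seed, " sided=", mc@sided),
        paste0("# binIndex=", paste(mc@binIndex, collapse = ","))), con)
    m <- maskedRho(mc)
    idx <- which(m != 0 & upper.tri(m, diag = TRUE), arr.ind = TRUE)
    df <- data.frame(bin_i = idx[, 1], bin_j = idx[, 2],
                     masked_rho = m[idx])
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeMaskedCorrelation
#' @param path TSV written by [writeMaskedCorrelation()].
#' @return for the reader, a [MaskedCorrelation-class] whose \code{rho} and
#'   \code{pval} carry only the retained entries (zeros / NA elsewhere).
#' @export
readMaskedCorrelation <- function(path) {
    hdr <- readLines(path, n = 2)
    kv <- strsplit(sub("^# ", "", hdr[1]), " ")[[1]]
    kv <- stats::setNames(sub("^[^=]*=", "", kv), sub("=.*$", "", kv))
    binIndex <- as.integer(strsplit(sub("^# binIndex=", "", hdr[2]),
                                    ",")[[1]])
    df <- utils::read.delim(path, skip = 2)
    n <- length(binIndex)
    m <- matrix(0, n, n)
    m[cbind(df$bin_i, df$bin_j)] <- df$masked_rho
    m[cbind(df$bin_j, df$bin_i)] <- df$masked_rho
    diag(m) <- 1
    pv <- matrix(NA_real_, n, n)
    new("MaskedCorrelation", chrom = kv[["chrom"]], group = kv[["group"]],
        binIndex = binIndex, rho = m, pval = pv, maskedRho = m,
        nPerm = as.integer(kv[["nPerm"]]), alpha = as.numeric(kv[["alpha"]]),
        seed = as.integer(kv[["seed"]]), sided = kv[["sided"]])
}
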