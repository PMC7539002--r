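#' Run the staged pipeline from a config
#'
#' Wires the stages — simulate, prep, call, compare, enrich — in dependency
#' order from a single YAML-style configuration (a file path or a named
#' list). Only stages listed in \code{config$stages} run; each consumes the
#' outputs of earlier stages in the same invocation. Every randomized stage
#' derives its seed from the single master seed (counter scheme, see
#' [dceConfig()]), all parameters and input digests are recorded in a JSON
#' run manifest, and existing outputs are never overwritten unless
#' \code{force}.
#'
#' Config keys (all optional unless a requested stage needs them):
#' \describe{
#'   \item{stages}{character vector among simulate, prep, call, compare,
#'     enrich.}
#'   \item{seed}{master seed (default 1).}
#'   \item{out}{output directory.}
#'   \item{gtf, counts, meta}{input paths for prep.}
#'   \item{scenario}{scenario name for simulate.}
#'   \item{groups}{group labels to call (default: all in metadata).}
#'   \item{reference}{reference group for compare (default healthy).}
#'   \item{call}{list of [dceConfig()] overrides (w, threshold, alpha,
#'     n_perm ...).}
#'   \item{sets, tracks, eplinks}{paths for enrich.}
#' }
#'
#' @param config path to a YAML file or a named list.
#' @param force overwrite existing outputs.
#' @return invisibly, the run manifest (also written to
#'   \code{out/manifest.json}).
#' @export
runPipeline <- function(config, force = FALSE) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    if (is.null(config$stages)) stop("config field 'stages' is required")
    out <- config$out
    if (is.null(out)) stop("config field 'out' is required")
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
    cc <- do.call(dceConfig, c(config$call,
                               list(seed = deriveSeed(seed, 10))))
    manifest <- list(tool = "dcescan",
                     version = as.character(utils::packageVersion("dcescan")),
                     config = config, seed = seed, stages = list())
    emit <- function(path) {
        if (file.exists(path) && !force)
            stop("refusing to overwrite ", path, " (use force = TRUE)")
        path
    }
    digest <- function(paths) as.list(tools::md5sum(paths))
    stageRecord <- function(name, t0, records, files) {
        manifest$stages[[name]] <<- list(
            seconds = round(as.numeric(Sys.time()) - t0, 2),
            records = records, outputs = files,
            digests = digest(unlist(files)))
    }

    genes <- counts <- meta <- NULL
    if ("simulate" %in% config$stages) {
        t0 <- as.numeric(Sys.time())
        scn <- if (is.null(config$scenario)) "intact" else config$scenario
        cfg <- do.call(simConfig, c(config$sim,
                                    list(seed = deriveSeed(seed, 1))))
        sc <- makeScenario(scn, cfg)
        genes <- simulateAnnotation(cfg)
        refC <- simulateCounts(genes, cfg, sc$refBlocks,
                               seed = deriveSeed(seed, 2),
                               samplePrefix = "ref_")
        qC <- simulateCounts(genes, cfg, sc$queryBlocks,
                             seed = deriveSeed(seed, 3),
                             samplePrefix = "query_")
        counts <- cbind(refC, qC)
        meta <- data.frame(
            sample_id = colnames(counts),
            group = rep(c("healthy", "low"), c(ncol(refC), ncol(qC))),
            sledai = rep(c(NA, 1), c(ncol(refC), ncol(qC))))
        files <- list(counts = emit(file.path(out, "sim_counts.tsv")),
                      meta = emit(file.path(out, "sim_meta.tsv")),
                      truth = emit(file.path(out, "sim_truth.json")))
        utils::write.table(data.frame(gene = rownames(counts), counts,
                                      check.names = FALSE),
                           files$counts, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        utils::write.table(meta, files$meta, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        jsonlite::write_json(sc, files$truth, auto_unbox = TRUE, digits = NA)
        stageRecord("simulate", t0, nrow(counts), files)
    }
    if (any(c("prep", "call", "compare", "enrich") %in% config$stages)) {
        t0 <- as.numeric(Sys.time())
        if (is.null(genes)) {
            if (is.null(config$gtf)) stop("stage prep needs 'gtf' ",
                                          "(or run the simulate stage first)")
            genes <- readGeneAnnotation(config$gtf)
            counts <- readCounts(config$counts)
            meta <- readSampleMetadata(config$meta)
        } else {
            meta <- stratifySamples(meta)
        }
        prep <- prepareExpression(counts, genes,
                                  lengthMode = if (is.null(config$length_mode))
                                      "span" else config$length_mode)
        binned <- binExpression(prep$expr, prep$genes, binSize = cc$binSize,
                                assignment = cc$assignment)
        files <- list(binned = emit(file.path(out, "binned.tsv")))
        writeBinnedExpression(binned, files$binned)
        stageRecord("prep", t0, nrow(prep$expr), files)
    }
    sets <- NULL
    if (any(c("call", "compare", "enrich") %in% config$stages)) {
        t0 <- as.numeric(Sys.time())
        groups <- if (!is.null(config$groups)) config$groups
                  else levels(droplevels(factor(meta$group)))
        sets <- list()
        files <- list()
        for (g in groups) {
            smp <- meta$sample_id[meta$group == g]
            sets[[g]] <- callDCEs(binned, smp, g, cc)
            bed <- emit(file.path(out, paste0(g, ".dce.bed")))
            tsv <- emit(file.path(out, paste0(g, ".dce.tsv")))
            writeDceBed(sets[[g]], bed)
            writeDceTable(sets[[g]], tsv)
            files[[g]] <- c(bed, tsv)
        }
        stageRecord("call", t0, vapply(sets, length, integer(1)), files)
    }
    if (any(c("compare", "enrich") %in% config$stages)) {
        t0 <- as.numeric(Sys.time())
        refGroup <- if (is.null(config$reference)) "healthy"
                    else config$reference
        if (!refGroup %in% names(sets))
            stop("reference group '", refGroup, "' was not called; run the ",
                 "call stage with it included")
        files <- list()
        reports <- list()
        for (g in setdiff(names(sets), refGroup)) {
            rep <- classifyDCEs(sets[[refGroup]], sets[[g]],
                                intactJaccard = cc$intactJaccard,
                                tol = cc$binSize)
            reports[[g]] <- rep
            fn <- emit(file.path(out, paste0(g, ".dynamics.tsv")))
            utils::write.table(rbind(refLabels(rep), queryLabels(rep)), fn,
                               sep = "\t", quote = FALSE, row.names = FALSE)
            dt <- disruptorTable(rep, sets[[refGroup]], sets[[g]],
                                 prep$genes)
            fd <- emit(file.path(out, paste0(g, ".disruptors.tsv")))
            utils::write.table(dt, fd, sep = "\t", quote = FALSE,
                               row.names = FALSE)
            files[[g]] <- c(fn, fd)
        }
        stageRecord("compare", t0, length(reports), files)
    }
    if ("enrich" %in% config$stages) {
        t0 <- as.numeric(Sys.time())
        refGroup <- if (is.null(config$reference)) "healthy"
                    else config$reference
        elig <- eligibleBins(binned, meta$sample_id[meta$group == refGroup])
        res <- list()
        if (!is.null(config$sets)) {
            gs <- readGeneSets(config$sets)
            res$gene_sets <- lapply(gs, function(s)
                genesetEnrichment(sets[[refGroup]], s, prep$genes, elig,
                                  nPerm = cc$nPerm,
                                  seed = deriveSeed(seed, 20)))
        }
        if (!is.null(config$tracks)) {
            tr <- readTrack(config$tracks)
            res$tracks <- trackEnrichment(sets[[refGroup]], tr, elig,
                                          nPerm = cc$nPerm,
                                          seed = deriveSeed(seed, 21))
        }
        if (!is.null(config$eplinks)) {
            lk <- readEpLinks(config$eplinks)
            qg <- setdiff(names(sets), refGroup)[1]
            res$eplinks <- epDisruption(lk, sets[[refGroup]],
                                        sets[[qg]])$fractionDisrupted
        }
        fn <- emit(file.path(out, "enrichment.json"))
        jsonlite::write_json(res, fn, auto_unbox = TRUE, digits = NA,
                             force = TRUE)
        stageRecord("enrich", t0, length(res), list(enrich = fn))
    }
    manifest$call_config <- cc
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
    invisible(manifest)
}
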