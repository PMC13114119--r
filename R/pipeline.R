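#' Run the RB-TnSeq analysis pipeline on a simulated or loaded bundle
#'
#' Orchestrates the stages end to end and writes plain-text artifacts
#' with a manifest.  Stages:
#' \describe{
#'   \item{simulate}{generate a library bundle with ground truth and
#'     passage tallies for every configured condition}
#'   \item{qc}{barcode-map filtering and per-gene insertion statistics}
#'   \item{essential}{zero-insertion calling, repeat masking from the
#'     genome's own self-similarity, the low-density expansion, and the
#'     final core set}
#'   \item{fitness}{per-replicate scoring and replicate combination for
#'     each condition versus the T0 library}
#'   \item{report}{cardinality tables of every set produced}
#' }
#' Every output TSV carries a header comment with a parameter hash, so
#' re-running with an identical config reproduces identical numeric
#' columns.
#'
#' @param config A [simConfig()] (for `simulate`) plus cutoff overrides:
#'   entries `fc_thresh`, `p_thresh`, `max_frac`, `n_resamples`,
#'   `window_bp`, `psi` are honoured.
#' @param out_dir Output directory.
#' @param stages Character vector of stages to run (in order).
#' @param seed Global seed, fanned out deterministically to sub-stage
#'   seeds.
#' @return Named list of in-memory results per stage, invisibly.
#' @export
runPipeline <- function(config = simConfig(), out_dir = tempfile("rbtnfit_"),
                        stages = c("simulate", "qc", "essential", "fitness",
                                   "report"),
                        seed = 1L) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    seed <- as.integer(seed)
    cfg_vec <- unlist(config[vapply(config, is.atomic, logical(1))])
    phash <- sprintf("%08x", sum(utf8ToInt(paste(names(cfg_vec), cfg_vec,
                                                 collapse = ";")) *
                                 seq_along(utf8ToInt(paste(names(cfg_vec),
                                                           cfg_vec,
                                                           collapse = ";")))) %%
                              .Machine$integer.max)
    wtsv <- function(d, f) {
        path <- file.path(out_dir, f)
        con <- file(path, "w")
        writeLines(paste0("# rbtnfit param_hash=", phash, " seed=", seed), con)
        utils::write.table(d, con, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        close(con)
    }
    res <- list()
    fc_thresh <- config$fc_thresh %||% 2
    p_thresh <- config$p_thresh %||% 0.05
    max_frac <- config$max_frac %||% 0.05
    n_resamples <- config$n_resamples %||% 100
    window_bp <- config$window_bp %||% 10000
    psi <- config$psi %||% 0.5

    if ("simulate" %in% stages) {
        config$seed <- seed
        lib <- simulateLibrary(config)
        out_tallies <- list(lib$tally)
        for (ci in seq_along(config$conditions))
            out_tallies[[ci + 1L]] <- simulatePassage(
                lib, names(config$conditions)[ci], config,
                seed = seed + 1000L * ci)
        lib$tally <- do.call(combineTallies, out_tallies)
        writeBundle(lib, out_dir)
        res$library <- lib
    }
    lib <- res$library
    if (is.null(lib)) stop("missing upstream artifact: run 'simulate' ",
                           "first or load a bundle yourself")
    if ("qc" %in% stages) {
        flt <- filterBarcodeMap(lib$map, lib$index)
        st <- geneInsertionStats(flt$map, lib$genes, lib$index,
                                 config$head_frac, config$tail_frac)
        wtsv(flt$report, "qc_rejections.tsv")
        wtsv(st$stats, "gene_insertion_stats.tsv")
        res$qc <- list(map = flt$map, report = flt$report, stats = st)
    }
    if ("essential" %in% stages) {
        if (is.null(res$qc)) stop("missing upstream artifact: ",
                                  "gene_insertion_stats.tsv (run 'qc')")
        zi <- callZeroInsertion(res$qc$map, lib$genes, lib$index,
                                config$head_frac, config$tail_frac)
        spans <- .self_repeat_spans(lib$genome)
        clusters <- clusterRepeatSpans(spans, lib$genome)
        excl <- repeatGeneExclusions(clusters, lib$genes)
        exp_set <- expandCandidates(res$qc$stats$stats, max_frac)
        calls <- finalizeCoreSet(zi$called, excl, character(),
                                 expanded = exp_set, no_data = zi$no_data)
        wtsv(data.frame(locus_tag = finalCore(calls)), "essential_core.tsv")
        wtsv(data.frame(locus_tag = expandedSet(calls)),
             "essential_expanded.tsv")
        res$essential <- list(calls = calls, clusters = clusters)
    }
    if ("fitness" %in% stages) {
        sig <- list()
        combined <- list()
        cd <- as.data.frame(colData(lib$tally))
        for (cond in names(config$conditions)) {
            sm <- cd[cd$condition == cond, , drop = FALSE]
            pairs <- data.frame(replicate = sm$replicate,
                                sample_in = "T0",
                                sample_out = sm$sample_id)
            rec <- fitnessPerReplicate(lib$tally, lib$genes, lib$index,
                                       pairs, config$head_frac,
                                       config$tail_frac, psi, n_resamples,
                                       window_bp, seed = seed + 77L)
            cmb <- combineReplicates(rec)
            sig[[cond]] <- selectSignificant(cmb, fc_thresh, p_thresh,
                                             label = cond)
            combined[[cond]] <- cmb
            wtsv(cmb, paste0("fitness_", cond, ".tsv"))
        }
        res$fitness <- list(combined = combined, significant = sig)
    }
    if ("report" %in% stages) {
        rows <- list()
        if (!is.null(res$essential)) {
            calls <- res$essential$calls
            rows <- c(rows, list(
                c("zero_insertion", length(zeroInsertion(calls))),
                c("repeat_excluded",
                  length(intersect(calls@repeatExcluded,
                                   zeroInsertion(calls)))),
                c("final_core", length(finalCore(calls))),
                c("expanded", length(expandedSet(calls)))))
        }
        if (!is.null(res$fitness))
            for (cond in names(res$fitness$significant)) {
                ss <- res$fitness$significant[[cond]]
                rows <- c(rows, list(
                    c(paste0(cond, "_decreased"), length(decreased(ss))),
                    c(paste0(cond, "_increased"), length(increased(ss)))))
            }
        rep_df <- data.frame(set = vapply(rows, `[`, character(1), 1),
                             n = as.integer(vapply(rows, `[`,
                                                   character(1), 2)))
        wtsv(rep_df, "report_cardinalities.tsv")
        res$report <- rep_df
    }
    manifest <- data.frame(
        key = c("param_hash", "seed", "stages", "out_dir"),
        value = c(phash, seed, paste(stages, collapse = ","), out_dir))
    wtsv(manifest, "manifest.tsv")
    invisible(res)
}

## all-vs-all repeat spans of a genome found by exact long-match
## screening of the planted repeat structure: windows of identical
## sequence discovered via k-mer anchoring (a lightweight stand-in for a
## full self-alignment, sufficient for block-identical repeat families)
.self_repeat_spans <- function(genome, min_len = 1000L, k = 31L) {
    spans <- NULL
    for (ct in names(genome)) {
        s <- as.character(genome[[ct]])
        n <- nchar(s)
        if (n < 2L * min_len) next
        starts <- seq_len(n - k + 1L)
        kmers <- substring(s, starts, starts + k - 1L)
        isdup <- duplicated(kmers) | duplicated(kmers, fromLast = TRUE)
        anchored <- starts[isdup]
        if (!length(anchored)) next
        ## merge runs of anchored positions into candidate spans
        d <- diff(anchored)
        brk <- c(0L, which(d > k), length(anchored))
        for (i in seq_len(length(brk) - 1L)) {
            a0 <- anchored[brk[i] + 1L]
            a1 <- anchored[brk[i + 1L]] + k - 1L
            if (a1 - a0 + 1L > min_len)
                spans <- rbind(spans, data.frame(
                    contig = ct, start = a0 - 1L, end = a1,
                    stringsAsFactors = FALSE))
        }
    }
    if (is.null(spans))
        data.frame(contig = character(), start = integer(),
                   end = integer(), stringsAsFactors = FALSE)
    else spans
}
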