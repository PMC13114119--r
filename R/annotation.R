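#' Assign COG categories from domain hits with per-model bitscore
#' thresholds
#'
#' A protein is assigned the functional category letters of every COG
#' model whose hit bitscore equals or exceeds that model's own threshold
#' (inclusive `>=`).  Hits to models missing from the threshold table
#' are skipped with a warning.  Raising any threshold can only remove
#' assignments, never add them.
#'
#' @param hits `data.frame` of domain hits: `protein`, `model`,
#'   `bitscore`, `evalue`.
#' @param thresholds `data.frame`: `model`, `threshold` (positive
#'   bitscore cutoff per model).
#' @param categories `data.frame`: `model`, `category` (one or more
#'   single-letter classes, e.g. `"EG"` assigns both E and G).
#' @param universe Optional character vector of all locus tags, used for
#'   coverage reporting and to emit unannotated genes with empty
#'   categories.
#' @return List with `annotation` (an [AnnotationTable-class]; PUL and
#'   CAZyme flags empty) and `summary` (`n_assigned`,
#'   `fraction_of_universe`).
#' @export
assignCOGs <- function(hits, thresholds, categories, universe = NULL) {
    thr <- stats::setNames(thresholds$threshold, thresholds$model)
    known <- hits$model %in% names(thr)
    if (any(!known))
        warning(sum(!known), " hit(s) to model(s) missing from the ",
                "threshold table skipped: ",
                paste(unique(hits$model[!known]), collapse = ", "))
    h <- hits[known, , drop = FALSE]
    keep <- h$bitscore >= unname(thr[h$model])
    h <- h[keep, , drop = FALSE]
    catmap <- stats::setNames(categories$category, categories$model)
    miss <- setdiff(unique(h$model), names(catmap))
    if (length(miss))
        stop("retained model(s) missing from the category map: ",
             paste(miss, collapse = ", "))
    letters_of <- function(models) {
        l <- unlist(strsplit(unname(catmap[unique(models)]), ""))
        paste(sort(unique(l)), collapse = ",")
    }
    assigned <- vapply(split(h$model, h$protein), letters_of, character(1))
    tags <- if (is.null(universe)) names(assigned) else universe
    cogs <- stats::setNames(rep("", length(tags)), tags)
    common <- intersect(tags, names(assigned))
    cogs[common] <- assigned[common]
    n_assigned <- sum(nzchar(cogs))
    list(annotation = AnnotationTable(tags, unname(cogs)),
         summary = list(n_assigned = n_assigned,
                        fraction_of_universe = n_assigned / length(tags)))
}

#' TPM normalization and expression ranking
#'
#' `TPM_i = 1e6 * (c_i / L_i) / sum_j (c_j / L_j)` per sample, so each
#' sample's TPM column sums to one million; ranks are descending by TPM
#' (rank 1 = most highly expressed) with average ranks on ties, computed
#' on the per-gene mean TPM when there are several samples.
#'
#' @param counts Numeric matrix (genes x samples) or vector of read
#'   counts.
#' @param lengths Gene lengths in bp (> 0).
#' @param locus_tag Optional gene ids (defaults to rownames).
#' @return `data.frame`: `locus_tag`, one `tpm_*` column per sample,
#'   `mean_tpm`, `rank`.
#' @export
tpmRank <- function(counts, lengths, locus_tag = NULL) {
    counts <- as.matrix(counts)
    stopifnot(length(lengths) == nrow(counts), all(lengths > 0))
    if (is.null(locus_tag))
        locus_tag <- rownames(counts) %||% sprintf("g%04d",
                                                   seq_len(nrow(counts)))
    tpm <- apply(counts, 2, function(cc) {
        rate <- cc / lengths
        tot <- sum(rate)
        if (tot <= 0)
            stop("all-zero counts in a sample; TPM undefined")
        1e6 * rate / tot
    })
    tpm <- matrix(tpm, nrow = nrow(counts))
    colnames(tpm) <- paste0("tpm_",
                            colnames(counts) %||% seq_len(ncol(tpm)))
    mean_tpm <- rowMeans(tpm)
    out <- data.frame(locus_tag = locus_tag, tpm,
                      mean_tpm = mean_tpm,
                      rank = rank(-mean_tpm, ties.method = "average"),
                      stringsAsFactors = FALSE)
    out[order(out$rank), , drop = FALSE]
}
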