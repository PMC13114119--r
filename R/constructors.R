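#' Construct a GeneTable
#'
#' @param locus_tag,contig,start,end,strand Vectors of equal length; `start`
#'   and `end` are 0-based half-open.
#' @param is_coding Logical; defaults to `TRUE`.
#' @param product Free-text product description; defaults to `""`.
#' @return A [GeneTable-class] object.
#' @export
GeneTable <- function(locus_tag, contig, start, end, strand,
                      is_coding = TRUE, product = "") {
    g <- data.frame(locus_tag = as.character(locus_tag),
                    contig = as.character(contig),
                    start = as.integer(start), end = as.integer(end),
                    strand = as.character(strand),
                    is_coding = rep_len(as.logical(is_coding),
                                        length(locus_tag)),
                    product = rep_len(as.character(product),
                                      length(locus_tag)),
                    stringsAsFactors = FALSE)
    new("GeneTable", genes = g)
}

#' Construct a TASiteIndex
#'
#' @param sites Named list of integer vectors (0-based T positions), one
#'   element per contig; each vector is sorted if needed.
#' @return A [TASiteIndex-class] object.
#' @export
TASiteIndex <- function(sites) {
    sites <- lapply(sites, function(v) sort(unique(as.integer(v))))
    new("TASiteIndex", sites = sites)
}

#' Construct a BarcodeMap
#'
#' @param barcode,contig,position,strand Vectors of equal length.
#' @param n_sites Number of distinct sites each barcode mapped to
#'   (default 1).
#' @return A [BarcodeMap-class] object.
#' @export
BarcodeMap <- function(barcode, contig, position, strand,
                       n_sites = 1L) {
    m <- data.frame(barcode = as.character(barcode),
                    contig = as.character(contig),
                    position = as.integer(position),
                    strand = as.character(strand),
                    n_sites = rep_len(as.integer(n_sites), length(barcode)),
                    stringsAsFactors = FALSE)
    new("BarcodeMap", map = m)
}

#' Construct a TATally
#'
#' @param counts Numeric matrix, TA sites in rows, samples in columns.
#' @param contig,position Row coordinates (0-based T position).
#' @param samples `data.frame` with columns `sample_id`, `condition`,
#'   `replicate`, `day`; one row per column of `counts`.
#' @return A [TATally-class] object with assay `"counts"`.
#' @export
TATally <- function(counts, contig, position, samples) {
    counts <- as.matrix(counts)
    stopifnot(nrow(samples) == ncol(counts))
    colnames(counts) <- samples$sample_id
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        rowData = DataFrame(contig = as.character(contig),
                            position = as.integer(position)),
        colData = DataFrame(samples, row.names = samples$sample_id))
    new("TATally", se)
}

#' Construct an AnnotationTable
#'
#' @param locus_tag Character vector of gene ids.
#' @param cog_categories Comma-separated COG class letters per gene
#'   (`""` = unannotated).
#' @param pul_id PUL membership id or `NA`.
#' @param cazyme_flag Logical CAZyme (GH/PL/CE) flag.
#' @return An [AnnotationTable-class] object.
#' @export
AnnotationTable <- function(locus_tag, cog_categories = "",
                            pul_id = NA_character_, cazyme_flag = FALSE) {
    n <- length(locus_tag)
    a <- data.frame(locus_tag = as.character(locus_tag),
                    cog_categories = rep_len(as.character(cog_categories), n),
                    pul_id = rep_len(as.character(pul_id), n),
                    cazyme_flag = rep_len(as.logical(cazyme_flag), n),
                    stringsAsFactors = FALSE)
    new("AnnotationTable", ann = a)
}

#' Construct a SignificanceSet
#'
#' @param label Condition / comparison / cutoff provenance string.
#' @param decreased,increased Locus tags with significantly decreased /
#'   increased insertion abundance.
#' @return A [SignificanceSet-class] object.
#' @export
SignificanceSet <- function(label, decreased = character(),
                            increased = character()) {
    new("SignificanceSet", label = as.character(label),
        decreased = unique(as.character(decreased)),
        increased = unique(as.character(increased)))
}
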