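#' @name io
#' @title Readers and writers for the plain-text exchange formats
#' @description
#' All tables are tab-separated with a header row.  Coordinates in the
#' native TSV dialects are 0-based half-open (the same convention used
#' in memory); GFF3 input is converted from 1-based inclusive at the
#' reader.  Dialects:
#' \itemize{
#'   \item gene table: `locus_tag contig start end strand is_coding product`
#'   \item TA index: `contig position`
#'   \item barcode map: `barcode contig position strand n_sites`
#'   \item TA tally: `contig position <sample...>` plus a sample sidecar
#'     `sample_id condition replicate day`
#'   \item annotation: `locus_tag cog_categories pul_id cazyme_flag`
#' }
#' @param path,file File path.
#' @param x Object to write.
NULL

.read_tsv <- function(path, need, what) {
    if (!file.exists(path))
        stop(what, " file not found: ", path)
    d <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = "NA")
    miss <- setdiff(need, names(d))
    if (length(miss))
        stop("malformed ", what, " file '", path, "': missing column(s) ",
             paste(miss, collapse = ", "))
    d
}

.check_int <- function(d, cols, path) {
    for (cc in cols) {
        v <- suppressWarnings(as.integer(d[[cc]]))
        bad <- which(is.na(v) & !is.na(d[[cc]]))
        if (length(bad))
            stop("malformed row in '", path, "', line ", bad[1] + 1L,
                 ": column '", cc, "' is not an integer")
        d[[cc]] <- v
    }
    d
}

#' @rdname io
#' @export
readGeneTable <- function(path) {
    d <- .read_tsv(path, c("locus_tag", "contig", "start", "end", "strand",
                           "is_coding"), "gene table")
    d <- .check_int(d, c("start", "end"), path)
    GeneTable(d$locus_tag, d$contig, d$start, d$end, d$strand,
              as.logical(d$is_coding),
              if ("product" %in% names(d)) d$product else "")
}

#' @rdname io
#' @export
writeGeneTable <- function(x, path) {
    utils::write.table(genes(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read gene models from GFF3
#'
#' Keeps `gene` and `CDS` features carrying a `locus_tag` attribute (one
#' record per locus tag; `CDS` marks the gene as protein coding) and
#' converts the 1-based inclusive GFF3 coordinates to the package's
#' 0-based half-open convention.
#'
#' @param path GFF3 file.
#' @return A [GeneTable-class].
#' @export
#' @importFrom rtracklayer import
readGeneTableGFF3 <- function(path) {
    gr <- rtracklayer::import(path, format = "gff3")
    keep <- gr$type %in% c("gene", "CDS") & !is.na(gr$locus_tag)
    gr <- gr[keep]
    if (!length(gr))
        stop("no gene/CDS features with locus_tag in '", path, "'")
    d <- data.frame(locus_tag = gr$locus_tag,
                    contig = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    coding = gr$type == "CDS",
                    product = if (!is.null(gr$product)) as.character(gr$product)
                              else "",
                    stringsAsFactors = FALSE)
    d$product[is.na(d$product)] <- ""
    ## one row per locus tag; a CDS feature wins over its parent gene
    d <- d[order(d$locus_tag, !d$coding), ]
    d <- d[!duplicated(d$locus_tag), ]
    GeneTable(d$locus_tag, d$contig, d$start, d$end, d$strand, d$coding,
              d$product)
}

#' @rdname io
#' @export
readTAIndex <- function(path) {
    d <- .read_tsv(path, c("contig", "position"), "TA index")
    d <- .check_int(d, "position", path)
    TASiteIndex(split(d$position, d$contig))
}

#' @rdname io
#' @export
writeTAIndex <- function(x, path) {
    s <- taSites(x)
    d <- data.frame(contig = rep(names(s), lengths(s)),
                    position = unlist(s, use.names = FALSE))
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname io
#' @export
readBarcodeMap <- function(path) {
    d <- .read_tsv(path, c("barcode", "contig", "position", "strand",
                           "n_sites"), "barcode map")
    d <- .check_int(d, c("position", "n_sites"), path)
    BarcodeMap(d$barcode, d$contig, d$position, d$strand, d$n_sites)
}

#' @rdname io
#' @export
writeBarcodeMap <- function(x, path) {
    utils::write.table(barcodes(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname io
#' @param samples_path Sample metadata sidecar TSV.
#' @export
readTATally <- function(path, samples_path) {
    d <- .read_tsv(path, c("contig", "position"), "TA tally")
    d <- .check_int(d, "position", path)
    s <- .read_tsv(samples_path, c("sample_id", "condition", "replicate",
                                   "day"), "sample metadata")
    cnt_cols <- setdiff(names(d), c("contig", "position"))
    if (!setequal(cnt_cols, s$sample_id))
        stop("sample columns in '", path, "' do not match sample_id in '",
             samples_path, "'")
    counts <- as.matrix(d[, s$sample_id, drop = FALSE])
    if (anyNA(counts))
        stop("malformed TA tally '", path, "': non-numeric counts")
    TATally(counts, d$contig, d$position, s)
}

#' @rdname io
#' @export
writeTATally <- function(x, path, samples_path) {
    rd <- rowData(x)
    d <- data.frame(contig = rd$contig, position = rd$position,
                    as.data.frame(assay(x, "counts")), check.names = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(colData(x)), samples_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname io
#' @export
readAnnotationTable <- function(path) {
    d <- .read_tsv(path, c("locus_tag", "cog_categories", "pul_id",
                           "cazyme_flag"), "annotation table")
    d$cog_categories[is.na(d$cog_categories)] <- ""
    AnnotationTable(d$locus_tag, d$cog_categories, d$pul_id,
                    as.logical(d$cazyme_flag))
}

#' @rdname io
#' @export
writeAnnotationTable <- function(x, path) {
    utils::write.table(annotations(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Load and cross-validate a complete analysis bundle
#'
#' Reads the gene table, TA index, barcode map, tally (+ sample sidecar)
#' and optional annotation table, and validates cross-references: every
#' tally site and every single-site barcode position must be a member of
#' the TA index, and every gene contig must appear in the index.  Row and
#' column counts are reported via `message()`.
#'
#' @param genes_path,ta_path,map_path,tally_path,samples_path,ann_path
#'   File paths (`ann_path` may be `NULL`).
#' @return A named list with elements `genes`, `index`, `map`, `tally`
#'   and (optionally) `annotation`.
#' @export
loadBundle <- function(genes_path, ta_path, map_path, tally_path,
                       samples_path, ann_path = NULL) {
    gt <- readGeneTable(genes_path)
    idx <- readTAIndex(ta_path)
    bm <- readBarcodeMap(map_path)
    tl <- readTATally(tally_path, samples_path)

    .member <- function(ct, pos) {
        ok <- logical(length(ct))
        for (c1 in unique(ct)) {
            i <- ct == c1
            ok[i] <- c1 %in% names(idx@sites) &
                pos[i] %in% idx@sites[[c1]]
        }
        ok
    }
    rd <- rowData(tl)
    bad <- which(!.member(rd$contig, rd$position))
    if (length(bad))
        stop("tally site not in TA index: ", rd$contig[bad[1]], ":",
             rd$position[bad[1]])
    m <- barcodes(bm)
    uniq <- m$n_sites == 1L
    badb <- which(uniq & !.member(m$contig, m$position))
    if (length(badb))
        stop("barcode '", m$barcode[badb[1]],
             "' maps to a position absent from the TA index: ",
             m$contig[badb[1]], ":", m$position[badb[1]])
    for (ct in unique(genes(gt)$contig))
        if (!ct %in% names(idx@sites))
            stop("gene contig '", ct, "' not present in TA site index")
    empty <- colnames(tl)[colSums(assay(tl, "counts")) == 0]
    if (length(empty))
        message("note: sample column(s) with zero total counts: ",
                paste(empty, collapse = ", "))
    message(sprintf("bundle: %d genes, %d TA sites, %d barcodes, %d x %d tally",
                    nrow(genes(gt)), sum(lengths(taSites(idx))),
                    nrow(m), nrow(tl), ncol(tl)))
    out <- list(genes = gt, index = idx, map = bm, tally = tl)
    if (!is.null(ann_path))
        out$annotation <- readAnnotationTable(ann_path)
    out
}

#' Write a complete analysis bundle
#'
#' Counterpart of [loadBundle()]; writes all components of a simulated or
#' loaded bundle into a directory using the native TSV dialects (and the
#' genome as FASTA when present).
#'
#' @param bundle Named list as returned by [simulateLibrary()] or
#'   [loadBundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
#' @importFrom Biostrings writeXStringSet
writeBundle <- function(bundle, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    p <- function(f) file.path(dir, f)
    writeGeneTable(bundle$genes, p("genes.tsv"))
    writeTAIndex(bundle$index, p("ta_index.tsv"))
    writeBarcodeMap(bundle$map, p("barcode_map.tsv"))
    writeTATally(bundle$tally, p("ta_tally.tsv"), p("samples.tsv"))
    if (!is.null(bundle$annotation))
        writeAnnotationTable(bundle$annotation, p("annotation.tsv"))
    if (!is.null(bundle$genome))
        writeXStringSet(bundle$genome, p("genome.fasta"))
    if (!is.null(bundle$truth)) {
        utils::write.table(geneTruth(bundle$truth), p("truth_genes.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(barcodeTruth(bundle$truth), p("truth_barcodes.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(dir)
}
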