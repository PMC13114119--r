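#' Internal TA sites of a gene, with terminus exclusion
#'
#' Insertions very close to a gene's ends are often tolerated even in
#' essential genes, so all insertion-density rules operate on the
#' "internal" span: TA sites whose strand-aware offset fraction from the
#' 5' end falls in `[head_frac, 1 - tail_frac)`.  The defaults exclude
#' the first 5% and last 10% of each gene.
#'
#' For a `+` strand gene the offset of a site at position `pos` is
#' `pos - start`; for a `-` strand gene it is `(end - 1) - pos`, so head
#' and tail exclusions follow the gene's own orientation.  Boundary
#' handling is half-open on both rule edges: a site is internal iff
#' `o/L >= head_frac` and `o/L < 1 - tail_frac`.
#'
#' @param genes A [GeneTable-class] (all genes) or a single-row gene
#'   `data.frame`.
#' @param index A [TASiteIndex-class].
#' @param head_frac,tail_frac Excluded 5' and 3' fractions of the gene
#'   length.  With both 0, all TA sites overlapping the gene span are
#'   returned.
#' @return For a [GeneTable-class]: a named list of integer vectors
#'   (genomic TA positions, ascending), one per gene.  For a single-row
#'   `data.frame`: one integer vector.
#' @examples
#' idx <- TASiteIndex(list(chr = c(30L, 500L, 949L)))
#' gt <- GeneTable("g1", "chr", 0L, 1000L, "+")
#' internalTASites(gt, idx)  # only the site at 500 survives
#' @export
internalTASites <- function(genes, index, head_frac = 0.05,
                            tail_frac = 0.10) {
    stopifnot(head_frac >= 0, tail_frac >= 0, head_frac + tail_frac < 1)
    g <- if (is(genes, "GeneTable")) genes(genes) else genes
    out <- vector("list", nrow(g))
    names(out) <- g$locus_tag
    for (i in seq_len(nrow(g))) {
        ct <- g$contig[i]
        if (!ct %in% names(index@sites))
            stop("contig '", ct, "' not present in TA site index")
        pos <- index@sites[[ct]]
        L <- g$end[i] - g$start[i]
        inspan <- pos[pos >= g$start[i] & pos < g$end[i]]
        o <- if (g$strand[i] == "+") inspan - g$start[i]
             else (g$end[i] - 1L) - inspan
        f <- o / L
        out[[i]] <- sort(inspan[f >= head_frac & f < 1 - tail_frac])
    }
    if (!is(genes, "GeneTable") && nrow(g) == 1L) out[[1L]] else out
}

#' Build a TA-site index by scanning a genome for TA dinucleotides
#'
#' @param genome A [Biostrings::DNAStringSet] (or path to a FASTA file).
#' @return A [TASiteIndex-class]; positions are 0-based coordinates of
#'   the T.
#' @export
#' @importFrom Biostrings DNAStringSet readDNAStringSet matchPattern
#' @importFrom IRanges start
taIndexFromGenome <- function(genome) {
    if (is.character(genome))
        genome <- readDNAStringSet(genome)
    sites <- lapply(seq_along(genome), function(i)
        as.integer(IRanges::start(matchPattern("TA", genome[[i]]))) - 1L)
    names(sites) <- sub("\\s.*$", "", names(genome))
    TASiteIndex(sites)
}
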