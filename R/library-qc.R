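#' Validate a barcode map against the TA-site index
#'
#' Applies the two library-validation rules: a barcode is retained only
#' if it mapped to exactly one insertion site and that site is a TA
#' dinucleotide in the index.  Rejections are data, not errors; they are
#' tallied by reason in the report.
#'
#' @param raw A [BarcodeMap-class] as parsed from insertion mapping.
#' @param index A [TASiteIndex-class].
#' @return List with `map` (the filtered [BarcodeMap-class]) and
#'   `report` (`data.frame` of `reason` in `{"multi-site", "non-TA",
#'   "retained"}` and `count`).  Idempotent: filtering a filtered map is
#'   a no-op.
#' @export
filterBarcodeMap <- function(raw, index) {
    m <- barcodes(raw)
    multi <- m$n_sites != 1L
    on_ta <- logical(nrow(m))
    for (ct in unique(m$contig)) {
        i <- m$contig == ct
        on_ta[i] <- ct %in% names(index@sites) &
            m$position[i] %in% index@sites[[ct]]
    }
    reason <- ifelse(multi, "multi-site",
                     ifelse(!on_ta, "non-TA", "retained"))
    keep <- reason == "retained"
    report <- data.frame(
        reason = c("multi-site", "non-TA", "retained"),
        count = c(sum(reason == "multi-site"), sum(reason == "non-TA"),
                  sum(keep)))
    list(map = new("BarcodeMap", map = m[keep, , drop = FALSE]),
         report = report)
}

#' Per-gene insertion summary statistics
#'
#' For each gene: the number of internal TA sites, how many of them
#' carry at least one mapped barcode, the fraction hit, the mean number
#' of distinct barcodes per internal TA site, and the total number of
#' distinct barcodes in the gene.  `full_span = TRUE` drops the terminus
#' exclusion for the insertion totals (whole-gene insertion counts).
#'
#' @param map A filtered [BarcodeMap-class].
#' @param genes A [GeneTable-class].
#' @param index A [TASiteIndex-class].
#' @param head_frac,tail_frac Terminus exclusion fractions (see
#'   [internalTASites()]).
#' @param full_span Count insertions over the whole gene span instead of
#'   the internal span.
#' @return List with `stats` (one row per gene: `locus_tag`,
#'   `n_internal_ta`, `n_internal_ta_hit`, `frac_ta_hit`,
#'   `mean_insertions_per_ta`, `total_insertions`; `frac_ta_hit` is `NA`
#'   when a gene has no internal TA sites) and `summary`
#'   (`mean_insertions_per_gene`, `min`, `max`, `n_genes`,
#'   `n_barcodes_in_genes`).
#' @export
geneInsertionStats <- function(map, genes, index, head_frac = 0.05,
                               tail_frac = 0.10, full_span = FALSE) {
    hf <- if (full_span) 0 else head_frac
    tf <- if (full_span) 0 else tail_frac
    sites <- internalTASites(genes, index, hf, tf)
    m <- barcodes(map)
    ## barcodes per site, per contig
    g <- genes(genes)
    per_site <- lapply(stats::setNames(unique(g$contig), unique(g$contig)),
                       function(ct) {
        mm <- m[m$contig == ct, , drop = FALSE]
        table(mm$position)
    })
    n <- nrow(g)
    n_ta <- n_hit <- tot <- integer(n)
    for (i in seq_len(n)) {
        s <- sites[[g$locus_tag[i]]]
        cnt <- per_site[[g$contig[i]]][as.character(s)]
        cnt[is.na(cnt)] <- 0L
        n_ta[i] <- length(s)
        n_hit[i] <- sum(cnt > 0)
        tot[i] <- sum(cnt)
    }
    stats <- data.frame(
        locus_tag = g$locus_tag, n_internal_ta = n_ta,
        n_internal_ta_hit = n_hit,
        frac_ta_hit = ifelse(n_ta > 0, n_hit / n_ta, NA_real_),
        mean_insertions_per_ta = ifelse(n_ta > 0, tot / n_ta, NA_real_),
        total_insertions = tot, stringsAsFactors = FALSE)
    list(stats = stats,
         summary = list(mean_insertions_per_gene = mean(tot),
                        min = min(tot), max = max(tot), n_genes = n,
                        n_barcodes_in_genes = sum(tot)))
}
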