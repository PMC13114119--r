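#' Normalize positional (replication) bias in a TA tally
#'
#' Chromosomal position biases barcode counts: replication makes
#' origin-proximal DNA more abundant in growing cells.  This transform
#' rescales each sample by fixed genomic windows: counts in a window are
#' multiplied by `median(window sums) / (window sum)`, so window totals
#' are levelled to their median.  Windows with zero total are left
#' untouched.  Per-sample totals before and after are reported via
#' `message()`.
#'
#' @param tally A raw (integer) [TATally-class].
#' @param window_bp Window width in bp (> 0).
#' @return A real-valued [TATally-class].
#' @export
normalizePositionalBias <- function(tally, window_bp = 10000) {
    if (window_bp <= 0)
        stop("window_bp must be > 0")
    rd <- rowData(tally)
    win <- paste(rd$contig, rd$position %/% as.integer(window_bp))
    a <- assay(tally, "counts")
    out <- a
    for (j in seq_len(ncol(a))) {
        sums <- rowsum(a[, j], win)
        med <- stats::median(sums[sums > 0, 1])
        fac <- ifelse(sums[, 1] > 0, med / sums[, 1], 1)
        out[, j] <- a[, j] * fac[match(win, rownames(sums))]
    }
    message(sprintf("positional normalization (%d bp windows): totals %s -> %s",
                    as.integer(window_bp),
                    paste(round(colSums(a)), collapse = ","),
                    paste(round(colSums(out)), collapse = ",")))
    TATally(out, rd$contig, rd$position, as.data.frame(colData(tally)))
}

#' Resample an input sample at the output sample's depth
#'
#' Simulates random loss of barcodes over time by repeatedly drawing
#' multinomial samples of the output sample's depth from the input
#' sample's site proportions.  The per-site mean over draws is the
#' depth-matched expected input count used as the reference in fitness
#' scoring.
#'
#' @param counts_in Numeric vector of per-site input counts (one sample).
#' @param depth_out Target depth: total count of the paired output
#'   sample.
#' @param n_resamples Number of multinomial draws (`R`).
#' @param seed Integer seed.
#' @return List with `expected` (per-site mean) and `draws` (R x sites
#'   matrix).
#' @export
resampleInput <- function(counts_in, depth_out, n_resamples = 100,
                          seed = 1L) {
    stopifnot(n_resamples >= 1, depth_out > 0)
    if (sum(counts_in) <= 0)
        stop("input sample has zero total count; cannot resample")
    set.seed(as.integer(seed))
    draws <- t(rmultinom(n_resamples, round(depth_out), counts_in))
    list(expected = colMeans(draws), draws = draws)
}

#' Two-sided Mann-Whitney p-value, exact for short vectors
#'
#' Rank-sum test of `x` against `y`.  When both vectors are shorter than
#' `exact_below` the null distribution of the rank sum is enumerated
#' exactly over all C(m+n, n) arrangements of the pooled (possibly tied)
#' values; otherwise the normal approximation with tie correction is
#' used.
#'
#' @param x,y Numeric vectors.
#' @param exact_below Use exact enumeration when both lengths are below
#'   this bound.
#' @return Two-sided p-value in (0, 1].
#' @export
rankSumTest <- function(x, y, exact_below = 8L) {
    n_x <- length(x); n_y <- length(y)
    if (!n_x || !n_y) return(NA_real_)
    r <- rank(c(x, y))
    W <- sum(r[seq_len(n_x)])
    if (n_x < exact_below && n_y < exact_below) {
        ## exact, tie-aware: enumerate all assignments of pooled ranks
        idx <- utils::combn(n_x + n_y, n_x)
        sums <- colSums(matrix(r[idx], nrow = n_x))
        mu <- n_x * (n_x + n_y + 1) / 2
        p <- mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
        return(min(1, p))
    }
    mu <- n_x * (n_x + n_y + 1) / 2
    n <- n_x + n_y
    ties <- table(r)
    sigma2 <- n_x * n_y / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- (W - mu) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
}

#' Per-gene fitness score for one replicate
#'
#' Computes the signed fold change and rank-sum p-value for one gene in
#' one input/output sample pair.  `FC = (sum out + psi) / (sum expected
#' in + psi)` over the gene's internal TA sites, where the expected
#' input counts are the depth-matched resampling means; the signed scale
#' is `s = FC` if `FC >= 1`, else `-1/FC`, so depletion and enrichment
#' are symmetric.  The p-value compares the observed per-site output
#' counts against the per-site expected input counts with
#' [rankSumTest()].
#'
#' @param out_counts Observed output counts at the gene's internal TA
#'   sites.
#' @param in_expected Depth-matched expected input counts at the same
#'   sites.
#' @param psi Pseudocount added to both sums.
#' @return List with `s`, `p`, `fc`; all `NA` (flagged `no_data`) when
#'   the gene has no internal sites.
#' @export
geneFitnessPerSample <- function(out_counts, in_expected, psi = 0.5) {
    if (!length(out_counts))
        return(list(s = NA_real_, p = NA_real_, fc = NA_real_,
                    no_data = TRUE))
    fc <- (sum(out_counts) + psi) / (sum(in_expected) + psi)
    s <- if (fc >= 1) fc else -1 / fc
    list(s = s, p = rankSumTest(out_counts, in_expected), fc = fc,
         no_data = FALSE)
}

#' Score per-gene fitness for all genes across replicate sample pairs
#'
#' The full per-replicate scoring stage: positional-bias normalization,
#' depth-matched resampling of each input sample, and per-gene signed
#' fold changes and rank-sum p-values for every (input, output) pair.
#'
#' @param tally A raw [TATally-class] containing all samples.
#' @param genes A [GeneTable-class].
#' @param index A [TASiteIndex-class].
#' @param pairs `data.frame` with columns `replicate`, `sample_in`,
#'   `sample_out` naming tally columns.
#' @param head_frac,tail_frac Terminus exclusion fractions.
#' @param psi Pseudocount.
#' @param n_resamples Multinomial resampling draws per pair.
#' @param window_bp Positional normalization window; `NULL` skips
#'   normalization.
#' @param seed Integer seed (fanned out per pair).
#' @return `data.frame` with one row per gene x replicate: `locus_tag`,
#'   `replicate`, `s`, `p`, `fc`, `n_internal_ta`.
#' @export
fitnessPerReplicate <- function(tally, genes, index, pairs,
                                head_frac = 0.05, tail_frac = 0.10,
                                psi = 0.5, n_resamples = 100,
                                window_bp = 10000, seed = 1L) {
    norm <- if (is.null(window_bp)) tally
            else normalizePositionalBias(tally, window_bp)
    rd <- rowData(norm)
    sites <- internalTASites(genes, index, head_frac, tail_frac)
    rowkey <- paste(rd$contig, rd$position)
    g <- genes(genes)
    site_rows <- lapply(seq_len(nrow(g)), function(i) {
        s <- sites[[g$locus_tag[i]]]
        if (!length(s)) return(integer(0))
        match(paste(g$contig[i], s), rowkey)
    })
    names(site_rows) <- g$locus_tag
    a <- assay(norm, "counts")
    res <- vector("list", nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
        cin <- a[, pairs$sample_in[k]]
        cout <- a[, pairs$sample_out[k]]
        rs <- resampleInput(cin, sum(cout), n_resamples,
                            seed = as.integer(seed) + k)
        expd <- rs$expected
        ng <- nrow(g)
        s_v <- p_v <- fc_v <- rep(NA_real_, ng)
        nta <- integer(ng)
        for (gi in seq_len(ng)) {
            sr <- site_rows[[gi]]
            nta[gi] <- length(sr)
            f <- geneFitnessPerSample(cout[sr], expd[sr], psi)
            s_v[gi] <- f$s; p_v[gi] <- f$p; fc_v[gi] <- f$fc
        }
        res[[k]] <- data.frame(locus_tag = g$locus_tag,
                               replicate = pairs$replicate[k],
                               s = s_v, p = p_v, fc = fc_v,
                               n_internal_ta = nta,
                               stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Combine per-replicate fitness records across animals
#'
#' Arithmetic-mean combination: `mean_s` and `mean_p` are means over the
#' replicates in which the gene was scored (genes missing from some
#' replicates are averaged over the rest and counted in the message).
#' The composite rank is the average of the rank by `mean_p` ascending
#' and the rank by `|mean_s|` descending, with average ranks on ties, so
#' half-integer ranks arise naturally.
#'
#' @param records Per-replicate table from [fitnessPerReplicate()].
#' @return `data.frame` with one row per gene: `locus_tag`,
#'   `n_replicates`, `mean_s`, `mean_p`, `rank`.
#' @export
combineReplicates <- function(records) {
    rec <- records[!is.na(records$s) & !is.na(records$p), , drop = FALSE]
    if (length(unique(rec$replicate)) < 2)
        stop("combining requires records from at least 2 replicates")
    sp <- split(rec, rec$locus_tag)
    out <- data.frame(
        locus_tag = names(sp),
        n_replicates = vapply(sp, nrow, integer(1)),
        mean_s = vapply(sp, function(d) mean(d$s), numeric(1)),
        mean_p = vapply(sp, function(d) mean(d$p), numeric(1)),
        stringsAsFactors = FALSE, row.names = NULL)
    nrep <- max(out$n_replicates)
    nmiss <- sum(out$n_replicates < nrep)
    if (nmiss)
        message(nmiss, " gene(s) scored in fewer than ", nrep,
                " replicates; combined over available replicates")
    r_p <- rank(out$mean_p, ties.method = "average")
    r_s <- rank(-abs(out$mean_s), ties.method = "average")
    out$rank <- (r_p + r_s) / 2
    out[order(out$rank), , drop = FALSE]
}

#' Select significant fitness genes from a combined table
#'
#' Strict cutoffs on the combined statistics: a gene is `decreased`
#' (insertions depleted; the gene contributes to fitness) when
#' `mean_s < 0`, `|mean_s| > fc_thresh` and `mean_p < p_thresh`;
#' `increased` analogously with `mean_s > 0`.  An optional
#' Benjamini-Hochberg adjusted column can be added by callers via
#' [stats::p.adjust]; selection here uses raw p-values.
#'
#' @param combined Table from [combineReplicates()].
#' @param fc_thresh Signed fold-change magnitude threshold (strict `>`).
#' @param p_thresh P-value threshold (strict `<`).
#' @param label Provenance label stored in the result.
#' @return A [SignificanceSet-class].
#' @export
selectSignificant <- function(combined, fc_thresh = 2, p_thresh = 0.05,
                              label = "fitness") {
    ok <- abs(combined$mean_s) > fc_thresh & combined$mean_p < p_thresh
    SignificanceSet(
        sprintf("%s |s|>%g p<%g", label, fc_thresh, p_thresh),
        decreased = combined$locus_tag[ok & combined$mean_s < 0],
        increased = combined$locus_tag[ok & combined$mean_s > 0])
}
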