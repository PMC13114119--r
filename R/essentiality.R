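#' Filter genome self-alignment hits to candidate repeat spans
#'
#' From a tabular self-alignment of the genome against itself, retains
#' hits with alignment length strictly greater than `min_len` and percent
#' identity strictly greater than `min_identity`.  The trivial full-length
#' self-vs-self diagonal (query span == subject span on the same contig)
#' is dropped, and reciprocal duplicates (A vs B and B vs A) are collapsed
#' to a single span pair.
#'
#' @param hits `data.frame` of self-hits with columns `qcontig`, `qstart`,
#'   `qend`, `scontig`, `sstart`, `send` (0-based half-open), `pident`,
#'   `length`.  See [readSelfHits()] for the reader that converts BLAST
#'   outfmt-6 coordinates.
#' @param min_len Minimum alignment length in bp (strict `>`).
#' @param min_identity Minimum percent identity (strict `>`).
#' @param drop_trivial_self Drop hits whose query and subject spans are
#'   identical.
#' @return The retained rows of `hits`.
#' @export
filterSelfHits <- function(hits, min_len = 1000, min_identity = 90,
                           drop_trivial_self = TRUE) {
    keep <- hits$length > min_len & hits$pident > min_identity
    h <- hits[keep, , drop = FALSE]
    if (drop_trivial_self) {
        triv <- h$qcontig == h$scontig & h$qstart == h$sstart &
            h$qend == h$send
        h <- h[!triv, , drop = FALSE]
    }
    ## collapse reciprocal duplicates: canonical order of the two spans
    a <- paste(h$qcontig, h$qstart, h$qend, sep = ":")
    b <- paste(h$scontig, h$sstart, h$send, sep = ":")
    key <- ifelse(a <= b, paste(a, b), paste(b, a))
    h <- h[!duplicated(key), , drop = FALSE]
    rownames(h) <- NULL
    h
}

#' Read BLAST tabular (outfmt 6) self-alignment hits
#'
#' Reads the 12-column tabular alignment dialect (`qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore`,
#' no header) and converts the 1-based inclusive coordinates to 0-based
#' half-open spans.  Subject hits on the minus strand (`sstart > send`)
#' are normalised to forward spans.
#'
#' @param path Tabular alignment file.
#' @return `data.frame` with columns `qcontig, qstart, qend, scontig,
#'   sstart, send, pident, length, evalue, bitscore`.
#' @export
readSelfHits <- function(path) {
    d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(d) < 12)
        stop("malformed tabular alignment file '", path,
             "': expected 12 columns, found ", ncol(d))
    names(d)[1:12] <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                        "gapopen", "qstart", "qend", "sstart", "send",
                        "evalue", "bitscore")
    s0 <- pmin(d$sstart, d$send)
    s1 <- pmax(d$sstart, d$send)
    data.frame(qcontig = d$qseqid, qstart = d$qstart - 1L, qend = d$qend,
               scontig = d$sseqid, sstart = s0 - 1L, send = s1,
               pident = d$pident, length = d$length, evalue = d$evalue,
               bitscore = d$bitscore, stringsAsFactors = FALSE)
}

## k-mer containment of the shorter sequence in the longer: fraction of
## the shorter sequence's k-mers present in the other sequence
.kmer_containment <- function(a, b, k = 11L) {
    ka <- .kmers(a, k); kb <- .kmers(b, k)
    if (!length(ka)) return(0)
    mean(ka %in% kb)
}

.kmers <- function(s, k) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

#' Greedily cluster repeat spans by sequence identity
#'
#' Spans are sorted by length descending; each span joins the first
#' existing cluster whose representative it matches at identity >= `c_id`
#' over >= `cov` of the shorter sequence, otherwise it founds a new
#' cluster.  Identity is estimated by k-mer containment (k = 11) of the
#' shorter sequence in the longer; when the estimate falls within +/- 5
#' percentage points of the `c_id` threshold it is refined by an exact
#' pairwise alignment ([Biostrings::pairwiseAlignment]).  The estimator
#' is deterministic, so cluster membership does not depend on input row
#' order.
#'
#' @param spans `data.frame` with columns `contig`, `start`, `end`
#'   (0-based half-open), e.g. the union of query and subject spans from
#'   [filterSelfHits()].
#' @param genome A [Biostrings::DNAStringSet] covering the spans.
#' @param c_id Identity threshold, fraction in (0, 1].
#' @param cov Coverage threshold (of the shorter sequence).
#' @return List of clusters; each has `representative` (a span row),
#'   `members` (`data.frame` of spans with `identity` and `coverage`
#'   columns versus the representative).
#' @export
#' @importFrom Biostrings pairwiseAlignment nmatch subseq
clusterRepeatSpans <- function(spans, genome, c_id = 0.90, cov = 0.90) {
    if (!nrow(spans)) return(list())
    spans <- unique(spans[, c("contig", "start", "end")])
    spans$len <- spans$end - spans$start
    spans <- spans[order(-spans$len, spans$contig, spans$start), ]
    rownames(spans) <- NULL
    getseq <- function(row) {
        if (!row$contig %in% names(genome))
            stop("missing sequence for contig '", row$contig, "'")
        as.character(subseq(genome[[row$contig]], row$start + 1L, row$end))
    }
    seqs <- vapply(seq_len(nrow(spans)), function(i) getseq(spans[i, ]),
                   character(1))
    clusters <- list()
    for (i in seq_len(nrow(spans))) {
        placed <- FALSE
        for (j in seq_along(clusters)) {
            rep_i <- clusters[[j]]$rep_index
            id <- .pair_identity(seqs[i], seqs[rep_i], c_id)
            if (id$identity >= c_id && id$coverage >= cov) {
                clusters[[j]]$member_index <- c(clusters[[j]]$member_index, i)
                clusters[[j]]$identity <- c(clusters[[j]]$identity,
                                            id$identity)
                clusters[[j]]$coverage <- c(clusters[[j]]$coverage,
                                            id$coverage)
                placed <- TRUE
                break
            }
        }
        if (!placed)
            clusters[[length(clusters) + 1L]] <-
                list(rep_index = i, member_index = i, identity = 1,
                     coverage = 1)
    }
    lapply(clusters, function(cl) {
        mem <- spans[cl$member_index, c("contig", "start", "end")]
        mem$identity <- cl$identity
        mem$coverage <- cl$coverage
        rownames(mem) <- NULL
        list(representative = spans[cl$rep_index,
                                    c("contig", "start", "end")],
             members = mem)
    })
}

## identity/coverage of the shorter sequence vs the longer: k-mer
## containment screen, alignment refinement near the decision boundary
.pair_identity <- function(a, b, c_id) {
    if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
    est <- .kmer_containment(a, b)
    if (abs(est - c_id) > 0.05)
        return(list(identity = est, coverage = if (est > 0) 1 else 0))
    pa <- pairwiseAlignment(a, b, type = "local")
    aligned <- nchar(pa)   # alignment length including gaps
    list(identity = if (aligned > 0) nmatch(pa) / aligned else 0,
         coverage = min(1, aligned / nchar(a)))
}

#' Genes excluded because they lie wholly inside repeat spans
#'
#' A gene is excluded only when its full span is contained in some
#' cluster member span; genes partially overlapping a repeat are kept
#' (partial genes at repeat edges are ignored by the masking rule).
#'
#' @param clusters Result of [clusterRepeatSpans()].
#' @param genes A [GeneTable-class].
#' @return Character vector of excluded locus tags.
#' @export
repeatGeneExclusions <- function(clusters, genes) {
    g <- genes(genes)
    out <- character(0)
    for (cl in clusters) {
        m <- cl$members
        for (i in seq_len(nrow(m))) {
            inside <- g$contig == m$contig[i] & g$start >= m$start[i] &
                g$end <= m$end[i]
            out <- c(out, g$locus_tag[inside])
        }
    }
    sort(unique(out))
}

#' Call genes with zero internal insertions
#'
#' Returns genes whose internal TA sites (terminus exclusion applied)
#' carry no mapped barcodes.  Genes without any internal TA site carry
#' no evidence either way; they are reported separately as `no_data`
#' and never called.
#'
#' @param map A filtered [BarcodeMap-class].
#' @param genes A [GeneTable-class].
#' @param index A [TASiteIndex-class].
#' @param head_frac,tail_frac Terminus exclusion fractions.
#' @return List with `called` (locus tags with zero internal insertions)
#'   and `no_data` (locus tags with no internal TA sites).
#' @export
callZeroInsertion <- function(map, genes, index, head_frac = 0.05,
                              tail_frac = 0.10) {
    st <- geneInsertionStats(map, genes, index, head_frac, tail_frac)$stats
    list(called = st$locus_tag[st$n_internal_ta > 0 &
                               st$total_insertions == 0],
         no_data = st$locus_tag[st$n_internal_ta == 0])
}

#' Assemble the final zero-insertion core set
#'
#' `final_core = zero_insertion - repeat_excluded - manual_excluded`,
#' with set-union-aware subtraction (a tag in both exclusion lists is
#' removed once).  Manual exclusions not present in the zero-insertion
#' set are ignored with a warning.  Cardinalities at each step are
#' reported via `message()`.
#'
#' @param zero_set Locus tags with zero internal insertions.
#' @param repeat_exclusions Locus tags inside repeat spans
#'   ([repeatGeneExclusions()]).
#' @param manual_exclusions Curated locus tags to remove (an input list;
#'   there is no rule for these).
#' @param expanded Optional expanded candidate set ([expandCandidates()]).
#' @param no_data Optional locus tags with no internal TA sites.
#' @return An [EssentialCallSet-class].
#' @export
finalizeCoreSet <- function(zero_set, repeat_exclusions = character(),
                            manual_exclusions = character(),
                            expanded = character(),
                            no_data = character()) {
    zero_set <- unique(as.character(zero_set))
    stray <- setdiff(manual_exclusions, zero_set)
    if (length(stray))
        warning("manual exclusion(s) not in the zero-insertion set, ",
                "ignored: ", paste(stray, collapse = ", "))
    final <- setdiff(zero_set, union(repeat_exclusions, manual_exclusions))
    message(sprintf("zero-insertion %d - repeat %d - manual %d -> core %d",
                    length(zero_set),
                    length(intersect(repeat_exclusions, zero_set)),
                    length(intersect(setdiff(manual_exclusions,
                                             repeat_exclusions), zero_set)),
                    length(final)))
    new("EssentialCallSet",
        zeroInsertion = zero_set,
        repeatExcluded = sort(unique(as.character(repeat_exclusions))),
        manualExcluded = sort(unique(as.character(manual_exclusions))),
        finalCore = sort(final),
        expanded = sort(unique(as.character(expanded))),
        noData = sort(unique(as.character(no_data))))
}

#' Expand candidates to genes with sparse residual insertions
#'
#' Genes in which at most `max_frac` of internal TA sites carry an
#' insertion (and that have at least one internal TA site).  This is a
#' superset of the zero-insertion genes with internal TA sites, and
#' recovers near-lethal genes whose few surviving insertions keep them
#' off the zero-insertion list.
#'
#' @param stats The `stats` table from [geneInsertionStats()] (computed
#'   with the matching terminus exclusions).
#' @param max_frac Maximum tolerated fraction of internal TA sites hit
#'   (inclusive `<=`).
#' @return Character vector of locus tags.
#' @export
expandCandidates <- function(stats, max_frac = 0.05) {
    sort(stats$locus_tag[stats$n_internal_ta > 0 &
                         !is.na(stats$frac_ta_hit) &
                         stats$frac_ta_hit <= max_frac])
}

#' Reciprocal-best-hit ortholog pairs from two hit tables
#'
#' A pair (a, b) is emitted when b is a's highest-bitscore hit in the
#' other proteome and a is b's highest-bitscore hit back.  Ties are
#' broken by smaller e-value, then lexicographically smaller subject id.
#'
#' @param hits_AB,hits_BA `data.frame`s with columns `query`, `subject`,
#'   `bitscore`, `evalue`.
#' @return `data.frame` with columns `a`, `b`.
#' @export
rbhOrthologs <- function(hits_AB, hits_BA) {
    best <- function(h) {
        h <- h[order(h$query, -h$bitscore, h$evalue, h$subject), ]
        h <- h[!duplicated(h$query), ]
        stats::setNames(h$subject, h$query)
    }
    ab <- best(hits_AB)
    ba <- best(hits_BA)
    a <- names(ab)
    mutual <- !is.na(ba[ab[a]]) & ba[ab[a]] == a
    mutual[is.na(mutual)] <- FALSE
    data.frame(a = a[mutual], b = unname(ab[a[mutual]]),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-strain concordance of essential-gene candidate sets
#'
#' Computes, for a focal genome with RBH ortholog maps to several
#' comparison strains, the set of focal genes whose orthologs are
#' essential in ALL comparison strains (the shared core), and how much
#' of that core is captured by the focal zero-insertion core list and by
#' the expanded low-insertion-density list.
#'
#' @param essential_by_strain Named list: per comparison strain, the
#'   character vector of its essential locus tags.
#' @param rbh_maps Named list (same names): per strain, an RBH pair
#'   table from [rbhOrthologs()] with `a` = focal gene, `b` = strain
#'   gene.
#' @param focal_core Focal zero-insertion core list.
#' @param focal_expanded Focal expanded candidate list.
#' @return List: `core` (focal genes essential in all strains),
#'   `n_core`, `in_core_list`/`n_in_core_list` (core captured by
#'   `focal_core`), `in_expanded`/`n_in_expanded`, and `increment` (core
#'   genes recovered by the expansion but absent from the core list).
#' @export
coreConcordance <- function(essential_by_strain, rbh_maps, focal_core,
                            focal_expanded) {
    strains <- names(essential_by_strain)
    miss <- setdiff(strains, names(rbh_maps))
    if (length(miss))
        stop("missing RBH map for strain(s): ", paste(miss, collapse = ", "))
    core <- NULL
    for (s in strains) {
        m <- rbh_maps[[s]]
        ess_focal <- m$a[m$b %in% essential_by_strain[[s]]]
        core <- if (is.null(core)) ess_focal else intersect(core, ess_focal)
    }
    core <- sort(unique(core))
    in_core <- intersect(core, focal_core)
    in_exp <- intersect(core, focal_expanded)
    list(core = core, n_core = length(core),
         in_core_list = sort(in_core), n_in_core_list = length(in_core),
         in_expanded = sort(in_exp), n_in_expanded = length(in_exp),
         increment = sort(setdiff(in_exp, in_core)))
}
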