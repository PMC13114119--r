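#' Configuration for the synthetic RB-TnSeq library simulator
#'
#' Builds the parameter list consumed by [simulateLibrary()] and
#' [simulatePassage()].  Defaults describe a desk-scale but informative
#' library: 1000 genes of ~3 kb, 8 TA sites/kb, 50,000 barcodes, a
#' transit bottleneck of 1e5 cells, 2e6 reads/sample, 10 generations of
#' growth per passage and 5 replicate animals.
#'
#' Per-condition fitness effects are point-mass components: each element
#' of `conditions` is a list of components `list(n = <gene count>,
#' value = <w>)` (or `list(n =, mean =, sd =)` for a normal component);
#' the named genes are drawn without replacement from non-essential,
#' non-repeat genes and all remaining genes get `w = 0`.  `w` is log2
#' fitness per generation: a mutant in a gene with `w = -1` halves in
#' relative abundance each generation.
#'
#' @param n_genes Number of regular genes.
#' @param mean_gene_length Mean gene length in bp.
#' @param ta_density TA sites per kb.
#' @param n_barcodes Library size (barcoded mutants).
#' @param essential_fraction Fraction of regular genes that are
#'   essential (receive no internal insertions).
#' @param generations Generations of growth per passage (`G`).
#' @param bottleneck Bottleneck population size in cells (`B`).
#' @param depth Sequencing depth per sample (`D`).
#' @param n_replicates Replicate animals per condition.
#' @param n_repeat_families,repeat_length,repeat_copies Planted repeat
#'   families: each family is a sequence-identical block repeated
#'   `repeat_copies` times, each copy carrying one embedded (identical)
#'   gene; barcodes landing in a copy map ambiguously to all copies.
#' @param conditions Named list of fitness-effect component lists (see
#'   Details).
#' @param head_frac,tail_frac Terminus fractions; insertions in a gene's
#'   excluded termini are simulated as fitness-neutral.
#' @param max_per_site Placement feasibility cap (barcodes per TA site).
#' @param seed Integer seed for [simulateLibrary()].
#' @return A named list of class `"simConfig"`.
#' @export
simConfig <- function(n_genes = 1000, mean_gene_length = 3000,
                      ta_density = 8, n_barcodes = 50000,
                      essential_fraction = 0.05, generations = 10,
                      bottleneck = 1e5, depth = 2e6, n_replicates = 5,
                      n_repeat_families = 2, repeat_length = 2000,
                      repeat_copies = 3,
                      conditions = list(gut = list(list(n = 50, value = -1))),
                      head_frac = 0.05, tail_frac = 0.10,
                      max_per_site = 1000, seed = 1L) {
    cfg <- list(n_genes = n_genes, mean_gene_length = mean_gene_length,
                ta_density = ta_density, n_barcodes = n_barcodes,
                essential_fraction = essential_fraction,
                generations = generations, bottleneck = bottleneck,
                depth = depth, n_replicates = n_replicates,
                n_repeat_families = n_repeat_families,
                repeat_length = repeat_length,
                repeat_copies = repeat_copies, conditions = conditions,
                head_frac = head_frac, tail_frac = tail_frac,
                max_per_site = max_per_site, seed = as.integer(seed))
    stopifnot(n_genes > 0, mean_gene_length > 0, ta_density > 0,
              n_barcodes > 0, essential_fraction >= 0,
              essential_fraction <= 1, generations > 0, bottleneck >= 1,
              depth >= 1, n_replicates >= 1)
    class(cfg) <- c("simConfig", "list")
    cfg
}

## plant "TA" at chosen even offsets of a character vector that was
## scrubbed of accidental TA dinucleotides
.plant_ta <- function(chars, offsets) {
    chars[offsets + 1L] <- "T"
    chars[offsets + 2L] <- "A"
    chars
}

## background sequence with no TA dinucleotide: iid ACGT, then any A
## following a T is flipped to G (cannot create new TAs)
.background_seq <- function(len) {
    s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    i <- which(s[-len] == "T" & s[-1L] == "A")
    if (length(i)) s[i + 1L] <- "G"
    s
}

#' Simulate a barcoded transposon mutant library with known truth
#'
#' Generates a synthetic genome (single contig) with planted TA sites at
#' the configured density, regular genes separated by intergenic gaps,
#' and `n_repeat_families` planted repeat families of sequence-identical
#' blocks each embedding one gene.  Barcodes are placed uniformly over
#' all TA sites except the internal sites of essential genes; barcodes
#' landing inside a repeat block are emitted with multiplicity equal to
#' the family's copy number (they cannot be uniquely mapped).  Initial
#' barcode abundances are exponential weights (library skew) and the T0
#' tally is a single multinomial draw of size `depth`.
#'
#' @param config A [simConfig()] list.
#' @return Named list: `genome` (DNAStringSet), `genes` (GeneTable),
#'   `index` (TASiteIndex), `map` (BarcodeMap), `tally` (TATally, the T0
#'   sample), `truth` (SimTruth).  Deterministic given `config$seed`.
#' @export
#' @importFrom Biostrings DNAStringSet
#' @importFrom stats rexp rmultinom
simulateLibrary <- function(config = simConfig()) {
    set.seed(config$seed)
    gap <- 200L
    ## ---- layout ----
    glen <- pmax(300L, as.integer(round(stats::rnorm(
        config$n_genes, config$mean_gene_length,
        0.3 * config$mean_gene_length))))
    glen <- glen - glen %% 2L   # even lengths keep even-offset TA grid simple
    starts <- integer(config$n_genes)
    pos <- 0L
    for (i in seq_len(config$n_genes)) {
        pos <- pos + gap
        starts[i] <- pos
        pos <- pos + glen[i]
    }
    rep_starts <- list()
    for (f in seq_len(config$n_repeat_families)) {
        cs <- integer(config$repeat_copies)
        for (cc in seq_len(config$repeat_copies)) {
            pos <- pos + gap
            cs[cc] <- pos
            pos <- pos + as.integer(config$repeat_length)
        }
        rep_starts[[f]] <- cs
    }
    genome_len <- pos + gap

    ## ---- sequence and TA sites ----
    chars <- .background_seq(genome_len)
    n_ta_for <- function(len) max(2L, as.integer(round(len / 1000 *
                                                       config$ta_density)))
    pick_offsets <- function(len, n) {
        grid <- seq.int(0L, len - 2L, by = 2L)
        sort(sample(grid, min(n, length(grid))))
    }
    ta <- integer(0)
    gene_sites <- vector("list", config$n_genes)
    for (i in seq_len(config$n_genes)) {
        off <- pick_offsets(glen[i], n_ta_for(glen[i]))
        gene_sites[[i]] <- starts[i] + off
        ta <- c(ta, starts[i] + off)
    }
    ## intergenic gap sites (before each gene)
    for (i in seq_len(config$n_genes)) {
        off <- pick_offsets(gap, max(1L, as.integer(round(
            gap / 1000 * config$ta_density))))
        ta <- c(ta, starts[i] - gap + off)
    }
    ## plant gene/intergenic TA sites, then copy in repeat templates
    ## (one shared scrubbed-and-planted sequence per family, with one
    ## embedded gene per copy)
    chars <- .plant_ta(chars, ta)
    rep_tbl <- NULL
    rep_gene_rows <- NULL
    for (f in seq_len(config$n_repeat_families)) {
        rl <- as.integer(config$repeat_length)
        tmpl <- .background_seq(rl)
        t_off <- pick_offsets(rl, n_ta_for(rl))
        tmpl <- .plant_ta(tmpl, t_off)
        g0 <- 200L; g1 <- rl - 200L        # embedded gene span in template
        for (cc in seq_along(rep_starts[[f]])) {
            s0 <- rep_starts[[f]][cc]
            chars[(s0 + 1L):(s0 + rl)] <- tmpl
            ta <- c(ta, s0 + t_off)
            rep_gene_rows <- rbind(rep_gene_rows, data.frame(
                locus_tag = sprintf("rep%02d_c%d", f, cc),
                start = s0 + g0, end = s0 + g1,
                family = sprintf("repfam%02d", f),
                stringsAsFactors = FALSE))
            rep_tbl <- rbind(rep_tbl, data.frame(
                family = sprintf("repfam%02d", f),
                start = s0, end = s0 + rl, stringsAsFactors = FALSE))
        }
    }
    ta <- sort(unique(ta))
    ## scrub stray TA dinucleotides formed at segment boundaries without
    ## touching repeat-copy interiors (which must stay identical)
    n <- length(chars)
    stray <- setdiff(which(chars[-n] == "T" & chars[-1L] == "A") - 1L, ta)
    if (length(stray)) {
        in_rep <- rep(FALSE, length(stray))
        if (!is.null(rep_tbl))
            for (i in seq_len(nrow(rep_tbl)))
                in_rep <- in_rep | (stray + 1L >= rep_tbl$start[i] &
                                    stray + 1L < rep_tbl$end[i])
        chars[ifelse(in_rep, stray + 1L, stray + 2L)] <-
            ifelse(in_rep, "C", "G")
    }

    genome <- DNAStringSet(paste(chars, collapse = ""))
    names(genome) <- "chr1"

    ## ---- gene table ----
    reg <- data.frame(locus_tag = sprintf("gene%04d", seq_len(config$n_genes)),
                      contig = "chr1", start = starts,
                      end = starts + glen,
                      strand = sample(c("+", "-"), config$n_genes,
                                      replace = TRUE),
                      stringsAsFactors = FALSE)
    all_genes <- rbind(reg[, c("locus_tag", "start", "end", "strand",
                               "contig")],
                       if (!is.null(rep_gene_rows))
                           data.frame(locus_tag = rep_gene_rows$locus_tag,
                                      start = rep_gene_rows$start,
                                      end = rep_gene_rows$end,
                                      strand = "+", contig = "chr1",
                                      stringsAsFactors = FALSE))
    gt <- GeneTable(all_genes$locus_tag, all_genes$contig, all_genes$start,
                    all_genes$end, all_genes$strand, is_coding = TRUE,
                    product = "simulated")
    idx <- TASiteIndex(list(chr1 = ta))

    ## ---- truth: essentiality and fitness effects ----
    ess <- sample(reg$locus_tag,
                  round(config$essential_fraction * config$n_genes))
    truth_g <- data.frame(locus_tag = all_genes$locus_tag,
                          essential = all_genes$locus_tag %in% ess,
                          repeat_family = NA_character_,
                          stringsAsFactors = FALSE)
    if (!is.null(rep_gene_rows))
        truth_g$repeat_family[match(rep_gene_rows$locus_tag,
                                    truth_g$locus_tag)] <- rep_gene_rows$family
    assignable <- setdiff(reg$locus_tag, ess)
    for (cond in names(config$conditions)) {
        w <- stats::setNames(rep(0, nrow(truth_g)), truth_g$locus_tag)
        pool <- assignable
        for (comp in config$conditions[[cond]]) {
            picked <- sample(pool, comp$n)
            pool <- setdiff(pool, picked)
            w[picked] <- if (!is.null(comp$value)) comp$value
                         else stats::rnorm(comp$n, comp$mean, comp$sd)
        }
        truth_g[[paste0("w_", cond)]] <- unname(w[truth_g$locus_tag])
    }

    ## ---- barcode placement ----
    internal <- internalTASites(gt, idx, config$head_frac, config$tail_frac)
    ess_internal <- unlist(internal[ess], use.names = FALSE)
    allowed <- setdiff(ta, ess_internal)
    if (!length(allowed))
        stop("no TA sites available for barcode placement")
    if (config$n_barcodes > length(allowed) * config$max_per_site)
        stop("infeasible placement: ", config$n_barcodes,
             " barcodes exceed ", length(allowed), " sites x ",
             config$max_per_site, " per site")
    bpos <- sample(allowed, config$n_barcodes, replace = TRUE)
    bc <- .random_barcodes(config$n_barcodes)
    ## multiplicity: copies of the repeat family whose span contains the site
    mult <- rep(1L, config$n_barcodes)
    if (!is.null(rep_tbl)) {
        for (i in seq_len(nrow(rep_tbl))) {
            inrep <- bpos >= rep_tbl$start[i] & bpos < rep_tbl$end[i]
            mult[inrep] <- as.integer(config$repeat_copies)
        }
    }
    bmap <- BarcodeMap(bc, "chr1", bpos,
                       sample(c("+", "-"), config$n_barcodes, replace = TRUE),
                       mult)

    ## host gene = gene whose internal span contains the insertion
    site2gene <- rep(NA_character_, length(ta))
    names(site2gene) <- as.character(ta)
    for (lt in names(internal))
        site2gene[as.character(internal[[lt]])] <- lt
    host <- unname(site2gene[as.character(bpos)])
    weight <- rexp(config$n_barcodes)
    truth_b <- data.frame(barcode = bc, locus_tag = host, position = bpos,
                          init_weight = weight, stringsAsFactors = FALSE)

    ## ---- T0 tally ----
    t0 <- rmultinom(1, config$depth, weight)[, 1]
    counts <- .sum_by_site(t0, bpos, ta)
    tally <- TATally(matrix(counts, ncol = 1), "chr1", ta,
                     data.frame(sample_id = "T0", condition = "T0",
                                replicate = 0L, day = 0L,
                                stringsAsFactors = FALSE))
    truth <- new("SimTruth", genes = truth_g, barcodes = truth_b,
                 config = unclass(config))
    list(genome = genome, genes = gt, index = idx, map = bmap,
         tally = tally, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.random_barcodes <- function(n, len = 20L) {
    repeat {
        bc <- vapply(seq_len(n), function(i)
            paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                  collapse = ""), character(1))
        if (!anyDuplicated(bc)) return(bc)
    }
}

.sum_by_site <- function(counts, positions, all_sites) {
    s <- rowsum(counts, positions)
    out <- numeric(length(all_sites))
    m <- match(as.character(all_sites), rownames(s))
    hit <- !is.na(m)
    out[hit] <- s[m[hit], 1]
    out
}

#' Simulate one passage of the library under selection
#'
#' Emulates growth of the mutant pool through an animal (or broth
#' passage) for each replicate: (1) a transit bottleneck, one multinomial
#' draw of `bottleneck` cells over current barcode abundances; (2)
#' deterministic exponential growth, each barcode multiplied by
#' `2^(w * generations)` where `w` is the fitness effect of its host
#' gene (0 for intergenic, terminus and repeat insertions); (3)
#' sequencing, one multinomial draw of `depth` reads over the grown
#' proportions.  Reads are summed per TA site, so every emitted column
#' sums exactly to `depth`.
#'
#' @param library Result of [simulateLibrary()].
#' @param condition Name of a condition in the library's config.
#' @param config A [simConfig()]; defaults to the library's own.
#' @param seed Integer seed.
#' @param day Day label stored in the sample metadata.
#' @return A [TATally-class] with one column per replicate.
#' @export
simulatePassage <- function(library, condition = NULL, config = NULL,
                            seed = 1L, day = 7L) {
    truth <- library$truth
    if (is.null(config)) {
        config <- truth@config
        class(config) <- c("simConfig", "list")
    }
    set.seed(as.integer(seed))
    tb <- truth@barcodes
    tg <- truth@genes
    wcol <- paste0("w_", condition)
    w_gene <- if (!is.null(condition) && wcol %in% names(tg))
        stats::setNames(tg[[wcol]], tg$locus_tag)
    else stats::setNames(rep(0, nrow(tg)), tg$locus_tag)
    w_b <- ifelse(is.na(tb$locus_tag), 0, unname(w_gene[tb$locus_tag]))
    w_b[is.na(w_b)] <- 0
    all_sites <- taSites(library$index, "chr1")
    cols <- matrix(0, nrow = length(all_sites), ncol = config$n_replicates)
    for (r in seq_len(config$n_replicates)) {
        n1 <- rmultinom(1, config$bottleneck, tb$init_weight)[, 1]
        grown <- n1 * 2^(w_b * config$generations)
        if (sum(grown) <= 0)
            stop("bottleneck extinguished the population; increase bottleneck")
        n2 <- rmultinom(1, config$depth, grown)[, 1]
        cols[, r] <- .sum_by_site(n2, tb$position, all_sites)
    }
    ids <- sprintf("%s_d%d_rep%d", condition %||% "none", day,
                   seq_len(config$n_replicates))
    TATally(cols, "chr1", all_sites,
            data.frame(sample_id = ids, condition = condition %||% "none",
                       replicate = seq_len(config$n_replicates),
                       day = as.integer(day), stringsAsFactors = FALSE))
}

#' Column-bind TA tallies over identical site sets
#'
#' @param ... [TATally-class] objects with identical row coordinates.
#' @return A combined [TATally-class].
#' @export
combineTallies <- function(...) {
    tl <- list(...)
    rd <- rowData(tl[[1]])
    for (t2 in tl[-1])
        if (!identical(as.integer(rowData(t2)$position),
                       as.integer(rd$position)) ||
            !identical(as.character(rowData(t2)$contig),
                       as.character(rd$contig)))
            stop("tallies have different TA site rows")
    counts <- do.call(cbind, lapply(tl, assay, "counts"))
    samples <- do.call(rbind, lapply(tl, function(t2)
        as.data.frame(colData(t2))))
    rownames(samples) <- NULL
    TATally(counts, rd$contig, rd$position, samples)
}
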