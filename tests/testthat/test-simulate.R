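test_that("the simulator is deterministic under a fixed seed", {
    cfg <- simConfig(n_genes = 30, mean_gene_length = 800,
                     n_barcodes = 800, depth = 5e4, bottleneck = 5e3,
                     n_replicates = 2,
                     conditions = list(gut = list(list(n = 3, value = -1))),
                     seed = 99)
    a <- simulateLibrary(cfg)
    b <- simulateLibrary(cfg)
    expect_identical(as.character(a$genome), as.character(b$genome))
    expect_identical(barcodes(a$map), barcodes(b$map))
    expect_identical(SummarizedExperiment::assay(a$tally),
                     SummarizedExperiment::assay(b$tally))
    pa <- simulatePassage(a, "gut", seed = 5)
    pb <- simulatePassage(b, "gut", seed = 5)
    expect_identical(SummarizedExperiment::assay(pa),
                     SummarizedExperiment::assay(pb))
})

test_that("planted structure is respected: essentials empty, repeats ambiguous", {
    lib <- small_sim()
    tg <- geneTruth(lib$truth)
    internal <- internalTASites(lib$genes, lib$index)
    m <- barcodes(lib$map)

    ## essential genes carry no internal barcodes at all
    for (lt in tg$locus_tag[tg$essential])
        expect_length(intersect(m$position, internal[[lt]]), 0)

    ## the TA index matches a fresh scan of the emitted genome
    expect_identical(taSites(taIndexFromGenome(lib$genome), "chr1"),
                     taSites(lib$index, "chr1"))

    ## repeat families: 2 x 3 identical blocks; barcodes inside them have
    ## multiplicity equal to the copy number
    g <- genes(lib$genes)
    rep_genes <- g[grepl("^rep", g$locus_tag), ]
    expect_identical(nrow(rep_genes), 6L)
    seqs <- vapply(seq_len(nrow(rep_genes)), function(i)
        as.character(Biostrings::subseq(lib$genome[[1]],
                                        rep_genes$start[i] + 1L,
                                        rep_genes$end[i])), character(1))
    fam <- sub("_c\\d$", "", rep_genes$locus_tag)
    expect_length(unique(seqs[fam == "rep01"]), 1L)
    expect_length(unique(seqs[fam == "rep02"]), 1L)
    expect_false(seqs[fam == "rep01"][1] == seqs[fam == "rep02"][1])
    inrep <- m$position >= min(rep_genes$start) - 200L
    for (i in seq_len(nrow(rep_genes))) {
        inside <- m$position >= rep_genes$start[i] &
            m$position < rep_genes$end[i]
        if (any(inside)) expect_true(all(m$n_sites[inside] == 3L))
    }

    ## infeasible placement errors
    cfg_bad <- simConfig(n_genes = 5, mean_gene_length = 400,
                         n_barcodes = 1e6, max_per_site = 10,
                         conditions = list(x = list(list(n = 0, value = 0))),
                         seed = 1)
    expect_error(simulateLibrary(cfg_bad), "infeasible")
})

test_that("every emitted tally column sums exactly to the sequencing depth", {
    lib <- small_sim()
    cfg <- lib$config
    expect_identical(unname(colSums(SummarizedExperiment::assay(lib$tally))),
                     cfg$depth)
    expect_identical(unname(colSums(SummarizedExperiment::assay(lib$out))),
                     rep(cfg$depth, cfg$n_replicates))
})

test_that("neutral passage leaves per-gene abundances unchanged within sampling error", {
    cfg <- simConfig(n_genes = 60, mean_gene_length = 3000,
                     n_barcodes = 6000, bottleneck = 1e6, depth = 2e6,
                     n_replicates = 1, n_repeat_families = 0,
                     essential_fraction = 0,
                     conditions = list(null = list(list(n = 0, value = 0))),
                     seed = 31)
    lib <- simulateLibrary(cfg)
    out <- simulatePassage(lib, "null", seed = 32)
    internal <- internalTASites(lib$genes, lib$index)
    cin <- SummarizedExperiment::assay(lib$tally)[, 1]
    cout <- SummarizedExperiment::assay(out)[, 1]
    ta <- taSites(lib$index, "chr1")
    g <- genes(lib$genes)
    for (i in seq_len(nrow(g))) {
        s <- internal[[g$locus_tag[i]]]
        if (length(s) < 20) next
        r <- match(s, ta)
        expect_lt(abs(log2(sum(cout[r]) / sum(cin[r]))), 0.2)
    }
})

test_that("a strongly deleterious gene is depleted by the closed-form factor", {
    ## one gene at w = -1 over G = 10 generations: expected log2 depletion
    ## versus neutral is -10; bottleneck and sequencing noise stay within 1
    cfg <- simConfig(n_genes = 50, mean_gene_length = 3000,
                     n_barcodes = 5000, bottleneck = 1e6, depth = 2e6,
                     n_replicates = 3, n_repeat_families = 0,
                     essential_fraction = 0, generations = 10,
                     conditions = list(sel = list(list(n = 1, value = -1))),
                     seed = 41)
    lib <- simulateLibrary(cfg)
    out <- simulatePassage(lib, "sel", seed = 42)
    tg <- geneTruth(lib$truth)
    hit <- tg$locus_tag[tg$w_sel < 0]
    internal <- internalTASites(lib$genes, lib$index)
    ta <- taSites(lib$index, "chr1")
    cin <- SummarizedExperiment::assay(lib$tally)[, 1]
    r <- match(internal[[hit]], ta)
    for (j in 1:3) {
        cout <- SummarizedExperiment::assay(out)[, j]
        obs <- log2((sum(cout[r]) + 0.5) / (sum(cin[r]) + 0.5))
        expect_lt(abs(obs - (-10)), 1)
    }
})

test_that("a severe bottleneck inflates replicate-to-replicate dispersion", {
    base <- list(n_genes = 40, mean_gene_length = 1500, n_barcodes = 2000,
                 depth = 2e5, n_replicates = 5, n_repeat_families = 0,
                 essential_fraction = 0,
                 conditions = list(null = list(list(n = 0, value = 0))))
    mk <- function(B) do.call(simConfig, c(base, list(bottleneck = B,
                                                      seed = 55)))
    disp <- function(B) {
        lib <- simulateLibrary(mk(B))
        out <- simulatePassage(lib, "null", seed = 56)
        internal <- internalTASites(lib$genes, lib$index)
        ta <- taSites(lib$index, "chr1")
        cin <- SummarizedExperiment::assay(lib$tally)[, 1]
        a <- SummarizedExperiment::assay(out)
        v <- vapply(names(internal), function(lt) {
            r <- match(internal[[lt]], ta)
            if (!length(r)) return(NA_real_)
            stats::var(log2((colSums(a[r, , drop = FALSE]) + 1) /
                            (sum(cin[r]) + 1)))
        }, numeric(1))
        mean(v, na.rm = TRUE)
    }
    expect_gt(disp(50), disp(1e6))
})
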