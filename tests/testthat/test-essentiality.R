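test_that("self-hit filtering applies strict thresholds and drops the diagonal", {
    hits <- data.frame(
        qcontig = "c1", qstart = c(0L, 0L, 1000L, 5000L, 8000L),
        qend = c(10000L, 1000L, 2500L, 6500L, 9000L),
        scontig = "c1", sstart = c(0L, 3000L, 5000L, 1000L, 20000L),
        send = c(10000L, 4000L, 6500L, 2500L, 21000L),
        pident = c(100, 95, 95, 95, 89.5), length = c(10000L, 1000L,
                                                      1500L, 1500L, 1000L))
    out <- filterSelfHits(hits)
    ## diagonal dropped; 1000 bp hit dropped (strict >); 89.5% dropped;
    ## the reciprocal 1500 bp pair collapses to one row
    expect_identical(nrow(out), 1L)
    expect_identical(out$length, 1500L)

    ## boundary: just over both thresholds is retained
    h2 <- data.frame(qcontig = "c", qstart = 0L, qend = 1001L,
                     scontig = "c", sstart = 5000L, send = 6001L,
                     pident = 90.1, length = 1001L)
    expect_identical(nrow(filterSelfHits(h2)), 1L)
})

test_that("tabular alignment coordinates convert to 0-based half-open", {
    p <- withr::local_tempfile()
    writeLines(c("c1\tc1\t95.5\t1500\t60\t2\t11\t1510\t5001\t6500\t0.0\t2000",
                 "c1\tc1\t99.0\t1200\t10\t0\t1\t1200\t9200\t8001\t0.0\t2100"),
               p)
    h <- readSelfHits(p)
    expect_identical(h$qstart[1], 10L)
    expect_identical(h$qend[1], 1510L)
    ## minus-strand subject span normalised to forward
    expect_identical(h$sstart[2], 8000L)
    expect_identical(h$send[2], 9200L)
})

test_that("repeat clustering groups planted families and separates strangers", {
    set.seed(13)
    mk <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                            collapse = "")
    famA <- mk(2000); famB <- mk(2000)
    genome <- Biostrings::DNAStringSet(c(
        chr = paste0(mk(500), famA, mk(300), famA, mk(300), famA,
                     mk(400), famB, mk(300), famB, mk(500))))
    spansA <- c(500, 500 + 2300, 500 + 4600)
    spansB <- c(500 + 2000 + 300 + 2000 + 300 + 2000 + 400,
                500 + 2000 + 300 + 2000 + 300 + 2000 + 400 + 2300)
    spans <- data.frame(contig = "chr", start = c(spansA, spansB),
                        end = c(spansA, spansB) + 2000L)
    cl <- clusterRepeatSpans(spans, genome)
    sizes <- sort(vapply(cl, function(x) nrow(x$members), integer(1)))
    expect_identical(sizes, c(2L, 3L))

    ## order stability: permuting input rows changes nothing
    cl2 <- clusterRepeatSpans(spans[sample(nrow(spans)), ], genome)
    key <- function(cls) sort(vapply(cls, function(x)
        paste(sort(x$members$start), collapse = ","), character(1)))
    expect_identical(key(cl), key(cl2))

    ## two unrelated random sequences -> two singletons (oracle: their
    ## pairwise identity is near zero)
    g2 <- Biostrings::DNAStringSet(c(chr = paste0(mk(2000), mk(2000))))
    sp2 <- data.frame(contig = "chr", start = c(0L, 2000L),
                      end = c(2000L, 4000L))
    expect_length(clusterRepeatSpans(sp2, g2), 2L)

    ## six identical copies -> one cluster of six
    g3 <- Biostrings::DNAStringSet(c(chr = paste(rep(famA, 6),
                                                 collapse = "")))
    sp3 <- data.frame(contig = "chr", start = seq(0L, by = 2000L,
                                                  length.out = 6L),
                      end = seq(2000L, by = 2000L, length.out = 6L))
    cl3 <- clusterRepeatSpans(sp3, g3)
    expect_length(cl3, 1L)
    expect_identical(nrow(cl3[[1]]$members), 6L)
})

test_that("only genes fully inside repeat spans are masked", {
    clusters <- list(list(
        representative = data.frame(contig = "c", start = 0L, end = 1200L),
        members = data.frame(contig = "c", start = 0L, end = 1200L,
                             identity = 1, coverage = 1)))
    gt <- GeneTable(c("inside", "partial", "outside"), "c",
                    start = c(100L, 900L, 3000L),
                    end = c(400L, 1500L, 3600L), strand = "+")
    expect_identical(repeatGeneExclusions(clusters, gt), "inside")
})

test_that("zero-insertion calling honours the terminus exclusion", {
    ## one barcode at 3% of gene length: still called (head-excluded)
    idx <- TASiteIndex(list(c = c(30L, 500L)))
    gt <- GeneTable(c("headonly", "hit"), "c", c(0L, 0L), c(1000L, 1000L),
                    "+")
    gt2 <- GeneTable("headonly", "c", 0L, 1000L, "+")
    map1 <- BarcodeMap("AAAA", "c", 30L, "+", 1L)
    zi <- callZeroInsertion(map1, gt2, idx)
    expect_identical(zi$called, "headonly")
    map2 <- BarcodeMap("AAAA", "c", 500L, "+", 1L)
    zi2 <- callZeroInsertion(map2, gt2, idx)
    expect_length(zi2$called, 0L)

    ## simulated truth: planted essentials are all called
    lib <- small_sim()
    flt <- filterBarcodeMap(lib$map, lib$index)
    zi3 <- callZeroInsertion(flt$map, lib$genes, lib$index)
    tg <- geneTruth(lib$truth)
    expect_true(all(tg$locus_tag[tg$essential] %in% zi3$called))
})

test_that("core-set bookkeeping is union-aware set subtraction", {
    zero <- sprintf("z%03d", 1:100)
    repeats <- zero[1:20]
    manual <- zero[c(15:20, 25)]   # overlaps the repeat list
    calls <- suppressMessages(finalizeCoreSet(zero, repeats, manual))
    ## brute force: setdiff against the union
    expect_setequal(finalCore(calls), setdiff(zero, union(repeats, manual)))
    expect_length(finalCore(calls), 100 - 21)

    ## identity with empty exclusions
    expect_setequal(finalCore(suppressMessages(finalizeCoreSet(zero))), zero)

    ## stray manual exclusion warns and is ignored
    expect_warning(suppressMessages(finalizeCoreSet(zero, character(),
                                                    "not_in_zero")),
                   "not_in_zero")

    ## randomized brute-force property
    set.seed(77)
    for (i in 1:25) {
        z <- sample(letters, sample(5:20, 1))
        r <- sample(letters, sample(0:10, 1))
        m <- sample(letters, sample(0:10, 1))
        got <- finalCore(suppressWarnings(suppressMessages(
            finalizeCoreSet(z, r, m))))
        expect_setequal(got, setdiff(z, union(r, m)))
    }
})

test_that("low-density expansion uses an inclusive fraction cutoff", {
    st <- data.frame(locus_tag = c("a", "b", "c", "d"),
                     n_internal_ta = c(40L, 40L, 0L, 10L),
                     n_internal_ta_hit = c(2L, 3L, 0L, 0L),
                     frac_ta_hit = c(0.05, 0.075, NA, 0),
                     total_insertions = c(4L, 3L, 0L, 0L))
    got <- expandCandidates(st, 0.05)
    expect_setequal(got, c("a", "d"))  # 0.05 in (inclusive), 0.075 out,
                                       # no-TA gene never included
})

test_that("reciprocal best hits equal the brute-force mutual argmax", {
    ab <- data.frame(query = c("A1", "A1", "A2"),
                     subject = c("B1", "B2", "B1"),
                     bitscore = c(100, 90, 80), evalue = c(1e-50, 1e-40,
                                                           1e-30))
    ba <- data.frame(query = c("B1", "B2"), subject = c("A1", "A1"),
                     bitscore = c(95, 60), evalue = c(1e-45, 1e-20))
    got <- rbhOrthologs(ab, ba)
    expect_identical(got, data.frame(a = "A1", b = "B1",
                                     stringsAsFactors = FALSE))

    ## A1 -> B1 best but B1 -> A3 best (A3 has no forward hits): no pair
    ba2 <- data.frame(query = "B1", subject = "A3", bitscore = 95,
                      evalue = 1e-45)
    expect_identical(nrow(rbhOrthologs(ab, ba2)), 0L)

    ## random 20x20 score matrix, no ties: brute-force mutual argmax
    set.seed(5)
    sc <- matrix(sample(1:10000, 400), 20, 20)
    an <- sprintf("A%02d", 1:20); bn <- sprintf("B%02d", 1:20)
    ab3 <- data.frame(query = rep(an, each = 20), subject = rep(bn, 20),
                      bitscore = as.vector(t(sc)), evalue = 1e-10)
    ba3 <- data.frame(query = rep(bn, each = 20), subject = rep(an, 20),
                      bitscore = as.vector(sc), evalue = 1e-10)
    got3 <- rbhOrthologs(ab3, ba3)
    brute <- NULL
    for (i in 1:20) {
        j <- which.max(sc[i, ])
        if (which.max(sc[, j]) == i)
            brute <- rbind(brute, data.frame(a = an[i], b = bn[j],
                                             stringsAsFactors = FALSE))
    }
    expect_equal(got3[order(got3$a), ], brute[order(brute$a), ],
                 ignore_attr = TRUE)
})

test_that("cross-strain concordance counts match brute-force intersection", {
    set.seed(8)
    focal <- sprintf("F%03d", 1:120)
    strains <- paste0("S", 1:5)
    ess <- rbh <- list()
    for (s in strains) {
        orth <- sprintf("%s_%s", s, focal)
        keep <- sample(c(TRUE, FALSE), 120, replace = TRUE, prob = c(.9, .1))
        rbh[[s]] <- data.frame(a = focal[keep], b = orth[keep],
                               stringsAsFactors = FALSE)
        ess[[s]] <- sample(orth, 70)
    }
    core_focal <- sample(focal, 50)
    exp_focal <- union(core_focal, sample(focal, 30))
    got <- coreConcordance(ess, rbh, core_focal, exp_focal)
    ## brute force over every focal gene
    brute <- focal[vapply(focal, function(f) {
        all(vapply(strains, function(s) {
            b <- rbh[[s]]$b[rbh[[s]]$a == f]
            length(b) == 1 && b %in% ess[[s]]
        }, logical(1)))
    }, logical(1))]
    expect_setequal(got$core, brute)
    expect_identical(got$n_in_core_list, length(intersect(brute, core_focal)))
    expect_identical(got$n_in_expanded, length(intersect(brute, exp_focal)))
    expect_setequal(got$increment,
                    setdiff(intersect(brute, exp_focal),
                            intersect(brute, core_focal)))
    expect_error(coreConcordance(ess, rbh[1:4], core_focal, exp_focal),
                 "S5")
})
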