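test_that("positional normalization levels windowed totals", {
    samples <- data.frame(sample_id = "s1", condition = "x",
                          replicate = 1L, day = 0L)
    pos <- seq(0L, by = 500L, length.out = 60L)   # 3 windows of 10 kb

    ## spatially uniform counts: identity
    t1 <- TATally(matrix(rep(10, 60), ncol = 1), "c", pos, samples)
    n1 <- suppressMessages(normalizePositionalBias(t1, 10000))
    expect_equal(SummarizedExperiment::assay(n1)[, 1], rep(10, 60),
                 ignore_attr = TRUE)

    ## 2x linear gradient: window-sum coefficient of variation drops >= 50%
    grad <- seq(10, 20, length.out = 60)
    t2 <- TATally(matrix(grad, ncol = 1), "c", pos, samples)
    n2 <- suppressMessages(normalizePositionalBias(t2, 10000))
    cv <- function(x) stats::sd(x) / mean(x)
    wsum <- function(v) tapply(v, pos %/% 10000L, sum)
    expect_lt(cv(wsum(SummarizedExperiment::assay(n2)[, 1])),
              0.5 * cv(wsum(grad)))

    ## single-window genome: identity
    t3 <- TATally(matrix(grad, ncol = 1), "c", pos, samples)
    n3 <- suppressMessages(normalizePositionalBias(t3, 1e6))
    expect_equal(SummarizedExperiment::assay(n3)[, 1], grad,
                 ignore_attr = TRUE)

    expect_error(normalizePositionalBias(t1, 0), "window_bp")
})

test_that("depth-matched resampling reproduces multinomial expectations", {
    cin <- c(100, 300, 50, 550)
    rs <- resampleInput(cin, depth_out = 500, n_resamples = 1000, seed = 3)
    p <- cin / sum(cin)
    se <- sqrt(500 * p * (1 - p)) / sqrt(1000)
    expect_true(all(abs(rs$expected - 500 * p) <= 4 * se + 1e-9))

    ## conservation at R = 1 and matched depth
    rs1 <- resampleInput(cin, depth_out = sum(cin), n_resamples = 1,
                         seed = 3)
    expect_equal(sum(rs1$draws), sum(cin))

    ## seeded reproducibility
    expect_identical(resampleInput(cin, 500, 10, seed = 9)$draws,
                     resampleInput(cin, 500, 10, seed = 9)$draws)
    expect_error(resampleInput(c(0, 0), 100), "zero total")
})

test_that("the rank-sum test is exact for short vectors and matches enumeration", {
    ## canonical worked example: complete separation of 3 vs 3
    expect_equal(rankSumTest(c(1, 2, 3), c(4, 5, 6)), 2 / 20)
    ## identical vectors: p = 1
    expect_equal(rankSumTest(c(2, 2, 2), c(2, 2, 2)), 1)

    ## exact branch equals the independent U-statistic enumeration for
    ## every length pair up to (7,7), with ties present
    set.seed(21)
    for (m in c(2, 3, 5, 7)) for (n in c(2, 4, 7)) {
        x <- sample(0:4, m, replace = TRUE)
        y <- sample(0:4, n, replace = TRUE)
        expect_equal(rankSumTest(x, y), brute_mw_p(x, y),
                     info = paste(m, n))
    }

    ## long-vector branch agrees with the standard normal approximation
    set.seed(22)
    x <- rpois(30, 20); y <- rpois(25, 22)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = FALSE))$p.value
    expect_equal(rankSumTest(x, y), ref, tolerance = 1e-10)
})

test_that("per-gene scoring produces the symmetric signed fold change", {
    ## depth-matched sums 100 -> 20 with no pseudocount: FC 0.2, s = -5
    f <- geneFitnessPerSample(out_counts = c(10, 5, 5),
                              in_expected = c(40, 30, 30), psi = 0)
    expect_equal(f$fc, 0.2)
    expect_equal(f$s, -5)

    ## identical site vectors: s = 1 exactly, p = 1
    f2 <- geneFitnessPerSample(c(3, 4, 5), c(3, 4, 5), psi = 0.5)
    expect_equal(f2$s, 1)
    expect_equal(f2$p, 1)

    ## no internal sites: flagged, nothing scored
    f3 <- geneFitnessPerSample(numeric(0), numeric(0))
    expect_true(f3$no_data)
    expect_true(is.na(f3$p))
})

test_that("replicate combination averages and composite-ranks with ties", {
    rec <- data.frame(
        locus_tag = rep(c("g1", "g2", "g3"), each = 2),
        replicate = rep(1:2, 3),
        s = c(-4, -4, 2, 2, -4, -4),
        p = c(0.04, 0.06, 0.5, 0.7, 0.04, 0.06),
        fc = 1, n_internal_ta = 5L)
    cmb <- combineReplicates(rec)
    expect_equal(cmb$mean_p[cmb$locus_tag == "g1"], 0.05)
    ## g1 and g3 are identical: both get the tied half-integer rank 1.5
    expect_equal(cmb$rank[cmb$locus_tag %in% c("g1", "g3")], c(1.5, 1.5))

    ## permutation invariance in replicate order
    cmb2 <- combineReplicates(rec[sample(nrow(rec)), ])
    expect_equal(cmb[order(cmb$locus_tag), ],
                 cmb2[order(cmb2$locus_tag), ], ignore_attr = TRUE)

    ## random table: composite rank equals brute-force recomputation
    set.seed(14)
    rec3 <- data.frame(locus_tag = rep(sprintf("g%02d", 1:50), each = 2),
                       replicate = rep(1:2, 50),
                       s = sample(c(-1, 1), 100, TRUE) *
                           stats::runif(100, 1, 30),
                       p = stats::runif(100), fc = 1, n_internal_ta = 5L)
    cmb3 <- combineReplicates(rec3)
    agg_s <- tapply(rec3$s, rec3$locus_tag, mean)
    agg_p <- tapply(rec3$p, rec3$locus_tag, mean)
    brute <- (rank(agg_p) + rank(-abs(agg_s))) / 2
    expect_equal(cmb3$rank[match(names(agg_p), cmb3$locus_tag)],
                 unname(brute))

    expect_error(combineReplicates(rec[rec$replicate == 1, ]),
                 "2 replicates")
})

test_that("significance selection uses strict cutoffs in both directions", {
    tab <- data.frame(locus_tag = c("a", "b", "c", "d"),
                      n_replicates = 3L,
                      mean_s = c(-2.0, -4, 3, -5),
                      mean_p = c(0.01, 0.01, 0.04, 0.05),
                      rank = 1:4)
    sig <- selectSignificant(tab)
    expect_false("a" %in% decreased(sig))  # |s| not strictly > 2
    expect_true("b" %in% decreased(sig))
    expect_true("c" %in% increased(sig))
    expect_false("d" %in% decreased(sig))  # p not strictly < 0.05
})

test_that("scoring is invariant to a constant depth factor on the output sample", {
    lib <- small_sim()
    a <- SummarizedExperiment::assay(lib$all)
    cin <- a[, "T0"]
    cout <- a[, 2]
    internal <- internalTASites(lib$genes, lib$index)
    ta <- taSites(lib$index, "chr1")
    score <- function(scale) {
        co <- cout * scale
        rs <- resampleInput(cin, sum(co), n_resamples = 200, seed = 4)
        vapply(names(internal)[1:40], function(lt) {
            r <- match(internal[[lt]], ta)
            if (length(r) < 3) return(NA_real_)
            geneFitnessPerSample(co[r], rs$expected[r])$s
        }, numeric(1))
    }
    s1 <- score(1); s3 <- score(3)
    gene_sums <- vapply(names(internal)[1:40], function(lt)
        sum(cout[match(internal[[lt]], ta)]), numeric(1))
    big <- which(!is.na(s1) & gene_sums >= 50)
    expect_true(all(abs(s3[big] / s1[big] - 1) < 0.01))
})
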