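## Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

## small simulated library + one selective passage; ~100 genes, 1 kb,
## 10 planted depleted genes, 2 repeat families of 3 copies
small_sim <- function() {
    if (is.null(.fixture_cache$small)) {
        cfg <- simConfig(n_genes = 100, mean_gene_length = 1000,
                         n_barcodes = 4000, bottleneck = 1e4, depth = 2e5,
                         n_replicates = 3,
                         conditions = list(gut = list(list(n = 10,
                                                           value = -1))),
                         seed = 7)
        lib <- simulateLibrary(cfg)
        out <- simulatePassage(lib, "gut", seed = 11)
        lib$out <- out
        lib$all <- combineTallies(lib$tally, out)
        lib$config <- cfg
        .fixture_cache$small <- lib
    }
    .fixture_cache$small
}

## hand-built micro bundle: 3 genes on one contig, explicit TA sites
micro_bundle <- function() {
    idx <- TASiteIndex(list(c1 = as.integer(c(10, 50, 100, 150, 200, 250,
                                              300, 350, 420, 480))))
    gt <- GeneTable(c("gA", "gB", "gC"), "c1",
                    start = c(0L, 140L, 400L), end = c(120L, 380L, 500L),
                    strand = c("+", "-", "+"))
    map <- BarcodeMap(
        barcode = c("AAAA", "CCCC", "GGGG", "TTTT", "ACGT"),
        contig = "c1",
        position = c(50L, 100L, 200L, 250L, 420L),
        strand = "+", n_sites = 1L)
    list(index = idx, genes = gt, map = map)
}

## independent recount of per-gene internal insertion totals straight
## from the barcode-map rows (oracle for geneInsertionStats)
brute_gene_counts <- function(map, genes, index, head_frac = 0.05,
                              tail_frac = 0.10) {
    m <- barcodes(map)
    g <- genes(genes)
    out <- integer(nrow(g))
    names(out) <- g$locus_tag
    for (i in seq_len(nrow(g))) {
        L <- g$end[i] - g$start[i]
        n <- 0L
        for (j in seq_len(nrow(m))) {
            if (m$contig[j] != g$contig[i]) next
            p <- m$position[j]
            if (p < g$start[i] || p >= g$end[i]) next
            o <- if (g$strand[i] == "+") p - g$start[i]
                 else (g$end[i] - 1L) - p
            if (o / L >= head_frac && o / L < 1 - tail_frac) n <- n + 1L
        }
        out[i] <- n
    }
    out
}

## independent exact two-sided Mann-Whitney p via the U statistic
## (0.5 per tie), enumerating all C(m+n, m) group assignments
brute_mw_p <- function(x, y) {
    pool <- c(x, y)
    m <- length(x); n <- length(y)
    ustat <- function(a, b) sum(outer(a, b, ">")) +
        0.5 * sum(outer(a, b, "=="))
    u_obs <- ustat(x, y)
    combos <- utils::combn(m + n, m)
    us <- apply(combos, 2, function(ix) ustat(pool[ix], pool[-ix]))
    mean(abs(us - m * n / 2) >= abs(u_obs - m * n / 2) - 1e-9)
}
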