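#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

## Coordinates are 0-based half-open throughout the package; a TA site is
## identified by the coordinate of its T on the forward strand.  Readers
## convert from 1-based external formats (GFF3, BLAST tabular) at the
## boundary.

#' Gene models for a bacterial genome
#'
#' A validity-checked table of gene spans.  Coordinates are 0-based
#' half-open (`start` is the first base, `end` one past the last), so
#' `end - start` is the gene length in bp.
#'
#' @slot genes A `data.frame` with columns `locus_tag`, `contig`, `start`,
#'   `end`, `strand` (`"+"`/`"-"`), `is_coding` (logical), `product`.
#'
#' @seealso [GeneTable()] for the constructor, [internalTASites()].
#' @export
setClass("GeneTable", representation(genes = "data.frame"))

setValidity("GeneTable", function(object) {
    g <- object@genes
    need <- c("locus_tag", "contig", "start", "end", "strand", "is_coding",
              "product")
    if (!all(need %in% names(g)))
        return(paste("missing columns:",
                     paste(setdiff(need, names(g)), collapse = ", ")))
    if (anyDuplicated(g$locus_tag))
        return("locus_tag values must be unique")
    if (any(g$start >= g$end))
        return("start must be < end (0-based half-open)")
    if (!all(g$strand %in% c("+", "-")))
        return("strand must be '+' or '-'")
    TRUE
})

#' Index of TA dinucleotide positions
#'
#' Per-contig sorted positions of TA dinucleotides, recorded as the
#' 0-based coordinate of the T on the forward strand.  Every mapped
#' insertion position in a [BarcodeMap] or [TATally] must be a member.
#'
#' @slot sites Named list (one element per contig) of strictly increasing
#'   integer vectors.
#'
#' @export
setClass("TASiteIndex", representation(sites = "list"))

setValidity("TASiteIndex", function(object) {
    s <- object@sites
    if (is.null(names(s)) || any(names(s) == ""))
        return("site list must be named by contig")
    for (ct in names(s)) {
        v <- s[[ct]]
        if (length(v) && (anyNA(v) || is.unsorted(v, strictly = TRUE)))
            return(sprintf("positions on contig '%s' must be strictly increasing",
                           ct))
    }
    TRUE
})

#' Barcode-to-insertion-site assignments
#'
#' One row per barcode observed in insertion mapping.  `n_sites` records
#' how many distinct sites the barcode mapped to; a validated map (after
#' [filterBarcodeMap()]) contains only rows with `n_sites == 1` whose
#' position is a TA site.
#'
#' @slot map A `data.frame` with columns `barcode`, `contig`, `position`,
#'   `strand`, `n_sites`.
#'
#' @export
setClass("BarcodeMap", representation(map = "data.frame"))

setValidity("BarcodeMap", function(object) {
    m <- object@map
    need <- c("barcode", "contig", "position", "strand", "n_sites")
    if (!all(need %in% names(m)))
        return(paste("missing columns:",
                     paste(setdiff(need, names(m)), collapse = ", ")))
    if (nrow(m) && any(grepl("[^ACGT]", m$barcode)))
        return("barcodes must be strings over {A,C,G,T}")
    if (nrow(m) && any(m$n_sites < 1))
        return("n_sites must be >= 1")
    TRUE
})

#' TA-site by sample count matrix ("TA tally")
#'
#' The central count object of an RB-TnSeq screen: summed barcode read
#' counts per TA site (rows) per sample (columns), stored as a
#' [SummarizedExperiment::SummarizedExperiment] with row metadata
#' `contig`, `position` and column metadata `sample_id`, `condition`,
#' `replicate`, `day`.  A raw tally is integer-valued; positional-bias
#' normalization ([normalizePositionalBias()]) produces real values.
#'
#' @seealso [TATally()] for the constructor.
#' @export
setClass("TATally", contains = "SummarizedExperiment")

setValidity("TATally", function(object) {
    rd <- rowData(object)
    cd <- colData(object)
    if (!all(c("contig", "position") %in% names(rd)))
        return("rowData must contain 'contig' and 'position'")
    if (!all(c("sample_id", "condition", "replicate", "day") %in% names(cd)))
        return("colData must contain sample_id, condition, replicate, day")
    if (anyDuplicated(cd$sample_id))
        return("sample ids must be unique")
    a <- assay(object, "counts")
    if (any(a < 0))
        return("counts must be non-negative")
    TRUE
})

#' Per-gene functional annotation flags
#'
#' @slot ann A `data.frame` with columns `locus_tag`, `cog_categories`
#'   (comma-separated single-letter COG functional classes, `""` when
#'   unannotated), `pul_id` (polysaccharide utilization locus id or `NA`),
#'   `cazyme_flag` (logical: predicted glycoside hydrolase / polysaccharide
#'   lyase / carbohydrate esterase).
#'
#' @export
setClass("AnnotationTable", representation(ann = "data.frame"))

setValidity("AnnotationTable", function(object) {
    a <- object@ann
    need <- c("locus_tag", "cog_categories", "pul_id", "cazyme_flag")
    if (!all(need %in% names(a)))
        return(paste("missing columns:",
                     paste(setdiff(need, names(a)), collapse = ", ")))
    if (anyDuplicated(a$locus_tag))
        return("locus_tag values must be unique")
    bad <- grepl("[^A-Z,]", a$cog_categories)
    if (any(bad))
        return("cog_categories must be comma-separated capital letters")
    TRUE
})

#' Essential-gene candidate call set
#'
#' Bookkeeping object for zero-insertion calling: the raw zero-insertion
#' list, repeat-masked and manually removed tags, the final core list
#' (`zero - repeat - manual`), the relaxed candidate list from the
#' low-insertion-density expansion, and genes with no internal TA sites
#' (never called; reported separately).
#'
#' @export
setClass("EssentialCallSet", representation(
    zeroInsertion  = "character",
    repeatExcluded = "character",
    manualExcluded = "character",
    finalCore      = "character",
    expanded       = "character",
    noData         = "character"))

setValidity("EssentialCallSet", function(object) {
    extra <- setdiff(object@finalCore, object@zeroInsertion)
    if (length(extra))
        return("finalCore must be a subset of zeroInsertion")
    TRUE
})

#' Direction-tagged significant gene set
#'
#' Genes whose insertion mutants are significantly depleted (`decreased`
#' fitness-conferring genes) or enriched (`increased`) in a comparison,
#' with a label recording the condition and cutoffs used.
#'
#' @export
setClass("SignificanceSet", representation(
    label = "character", decreased = "character", increased = "character"))

setValidity("SignificanceSet", function(object) {
    if (length(intersect(object@decreased, object@increased)))
        return("decreased and increased sets must be disjoint")
    TRUE
})

#' Simulator ground truth
#'
#' Per-gene truth (essentiality, per-condition log2 fitness per
#' generation, repeat-family membership) and per-barcode truth (host
#' gene, initial abundance weight) for a simulated library, used in
#' parameter-recovery and calibration tests.
#'
#' @export
setClass("SimTruth", representation(
    genes = "data.frame", barcodes = "data.frame", config = "list"))
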