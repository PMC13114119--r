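#' @name accessors
#' @title Accessors for rbtnfit classes
#' @description Slot accessors; user code should use these rather than
#'   `@`.
#' @param x An rbtnfit object.
#' @param contig Optional contig name to restrict [taSites()] to.
NULL

#' @describeIn accessors Gene table as a `data.frame`.
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @export
setMethod("genes", "GeneTable", function(x) x@genes)

#' @describeIn accessors TA positions, as a named list (all contigs) or an
#'   integer vector (one contig).
#' @export
setGeneric("taSites", function(x, contig = NULL) standardGeneric("taSites"))

#' @export
setMethod("taSites", "TASiteIndex", function(x, contig = NULL) {
    if (is.null(contig))
        return(x@sites)
    if (!contig %in% names(x@sites))
        stop("contig '", contig, "' not present in TA site index")
    x@sites[[contig]]
})

#' @describeIn accessors Barcode map as a `data.frame`.
#' @export
setGeneric("barcodes", function(x) standardGeneric("barcodes"))

#' @export
setMethod("barcodes", "BarcodeMap", function(x) x@map)

#' @describeIn accessors Annotation table as a `data.frame`.
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @export
setMethod("annotations", "AnnotationTable", function(x) x@ann)

#' @describeIn accessors Decreased-direction locus tags.
#' @export
setGeneric("decreased", function(x) standardGeneric("decreased"))

#' @export
setMethod("decreased", "SignificanceSet", function(x) x@decreased)

#' @describeIn accessors Increased-direction locus tags.
#' @export
setGeneric("increased", function(x) standardGeneric("increased"))

#' @export
setMethod("increased", "SignificanceSet", function(x) x@increased)

#' @describeIn accessors Final core essential-candidate locus tags.
#' @export
setGeneric("finalCore", function(x) standardGeneric("finalCore"))

#' @export
setMethod("finalCore", "EssentialCallSet", function(x) x@finalCore)

#' @describeIn accessors Expanded (low-insertion-density) candidate tags.
#' @export
setGeneric("expandedSet", function(x) standardGeneric("expandedSet"))

#' @export
setMethod("expandedSet", "EssentialCallSet", function(x) x@expanded)

#' @describeIn accessors Zero-insertion locus tags (pre-masking).
#' @export
setGeneric("zeroInsertion", function(x) standardGeneric("zeroInsertion"))

#' @export
setMethod("zeroInsertion", "EssentialCallSet", function(x) x@zeroInsertion)

#' @describeIn accessors Per-gene simulator truth as a `data.frame`.
#' @export
setGeneric("geneTruth", function(x) standardGeneric("geneTruth"))

#' @export
setMethod("geneTruth", "SimTruth", function(x) x@genes)

#' @describeIn accessors Per-barcode simulator truth as a `data.frame`.
#' @export
setGeneric("barcodeTruth", function(x) standardGeneric("barcodeTruth"))

#' @export
setMethod("barcodeTruth", "SimTruth", function(x) x@barcodes)

setMethod("show", "GeneTable", function(object) {
    g <- object@genes
    cat("GeneTable with", nrow(g), "genes on",
        length(unique(g$contig)), "contig(s)\n")
    cat("  coding:", sum(g$is_coding), " length range:",
        paste(range(g$end - g$start), collapse = "-"), "bp\n")
})

setMethod("show", "TASiteIndex", function(object) {
    n <- vapply(object@sites, length, integer(1))
    cat("TASiteIndex:", sum(n), "TA sites on", length(n), "contig(s)\n")
})

setMethod("show", "BarcodeMap", function(object) {
    m <- object@map
    cat("BarcodeMap with", nrow(m), "barcodes (",
        sum(m$n_sites == 1L), "single-site )\n")
})

setMethod("show", "AnnotationTable", function(object) {
    a <- object@ann
    cat("AnnotationTable:", nrow(a), "genes;",
        sum(nzchar(a$cog_categories)), "COG-annotated;",
        sum(!is.na(a$pul_id)), "in PULs;",
        sum(a$cazyme_flag), "CAZymes\n")
})

setMethod("show", "EssentialCallSet", function(object) {
    cat("EssentialCallSet\n",
        " zero-insertion:  ", length(object@zeroInsertion), "\n",
        " repeat-excluded: ", length(object@repeatExcluded), "\n",
        " manual-excluded: ", length(object@manualExcluded), "\n",
        " final core:      ", length(object@finalCore), "\n",
        " expanded:        ", length(object@expanded), "\n",
        " no internal TA:  ", length(object@noData), "\n", sep = "")
})

setMethod("show", "SignificanceSet", function(object) {
    cat("SignificanceSet [", object@label, "]: ",
        length(object@decreased), " decreased, ",
        length(object@increased), " increased\n", sep = "")
})

setMethod("show", "SimTruth", function(object) {
    cat("SimTruth:", nrow(object@genes), "genes (",
        sum(object@genes$essential), "essential ),",
        nrow(object@barcodes), "barcodes\n")
})
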