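#' Refine a condition's significant gene set against control comparisons
#'
#' Removes from a condition's significant set (per direction) any gene
#' that is also significant in a time-matched healthy control comparison
#' (fitness change attributable to longer residence, not the condition)
#' or in an exposure-only broth control (response to the compound, not
#' to the induced host state).  Removal is direction-blind: a gene
#' significant in a control in either direction is removed from both
#' directions of the condition set.  The audit report lists every
#' removed gene with its reason, so
#' `|refined| + |removed| = |condition|` per direction.
#'
#' @param condition A [SignificanceSet-class] for the condition.
#' @param time_control A [SignificanceSet-class] for the healthy
#'   time-matched comparison (may be empty).
#' @param exposure_control A [SignificanceSet-class] for the in-broth
#'   exposure comparison (may be empty).
#' @return List with `refined` (a [SignificanceSet-class]) and `audit`
#'   (`data.frame` of `locus_tag`, `direction`, `removal_reason`).
#' @export
refineConditionSet <- function(condition,
                               time_control = SignificanceSet("none"),
                               exposure_control = SignificanceSet("none")) {
    tc <- union(decreased(time_control), increased(time_control))
    ec <- union(decreased(exposure_control), increased(exposure_control))
    audit <- NULL
    refine_dir <- function(genes, dir) {
        hit_tc <- intersect(genes, tc)
        hit_ec <- intersect(setdiff(genes, tc), ec)
        if (length(hit_tc))
            audit <<- rbind(audit, data.frame(
                locus_tag = hit_tc, direction = dir,
                removal_reason = "time-control", stringsAsFactors = FALSE))
        if (length(hit_ec))
            audit <<- rbind(audit, data.frame(
                locus_tag = hit_ec, direction = dir,
                removal_reason = "exposure-control",
                stringsAsFactors = FALSE))
        setdiff(genes, union(tc, ec))
    }
    dec <- refine_dir(decreased(condition), "decreased")
    inc <- refine_dir(increased(condition), "increased")
    refined <- SignificanceSet(paste0(condition@label, " [refined]"),
                               decreased = dec, increased = inc)
    if (is.null(audit))
        audit <- data.frame(locus_tag = character(),
                            direction = character(),
                            removal_reason = character(),
                            stringsAsFactors = FALSE)
    list(refined = refined, audit = audit)
}

#' Fraction of each COG category that is significant
#'
#' For each COG functional category and each direction: the number of
#' significant genes carrying the category divided by the number of
#' genes in the genome carrying it.  Genes with multiple categories
#' count in every one of them; unannotated genes are excluded from all
#' denominators.  Categories with zero genes are flagged with an `NA`
#' fraction.
#'
#' @param sig A [SignificanceSet-class].
#' @param ann An [AnnotationTable-class] covering the gene universe.
#' @return `data.frame` with columns `category`, `direction`,
#'   `numerator`, `denominator`, `fraction`.
#' @export
categoryFraction <- function(sig, ann) {
    a <- annotations(ann)
    cats <- strsplit(a$cog_categories, ",", fixed = TRUE)
    long <- data.frame(
        locus_tag = rep(a$locus_tag, lengths(cats)),
        category = unlist(cats), stringsAsFactors = FALSE)
    long <- long[nzchar(long$category), , drop = FALSE]
    all_cats <- sort(unique(long$category))
    denom <- table(factor(long$category, levels = all_cats))
    out <- NULL
    for (dir in c("decreased", "increased")) {
        g <- if (dir == "decreased") decreased(sig) else increased(sig)
        num <- table(factor(long$category[long$locus_tag %in% g],
                            levels = all_cats))
        out <- rbind(out, data.frame(
            category = all_cats, direction = dir,
            numerator = as.integer(num),
            denominator = as.integer(denom),
            fraction = ifelse(denom > 0, as.integer(num) /
                                         as.integer(denom), NA_real_),
            stringsAsFactors = FALSE))
    }
    rownames(out) <- NULL
    out
}

#' Count significant genes carrying annotation flags
#'
#' Union semantics: a gene counts if it carries any of the requested
#' flags (`"pul"`: member of a polysaccharide utilization locus;
#' `"cazyme"`: predicted glycoside hydrolase / polysaccharide lyase /
#' carbohydrate esterase).
#'
#' @param sig_genes Character vector of significant locus tags.
#' @param ann An [AnnotationTable-class].
#' @param flags Which flags to test, subset of `c("pul", "cazyme")`.
#' @return List with `count` and `genes`.
#' @export
annotationOverlapCount <- function(sig_genes, ann,
                                   flags = c("pul", "cazyme")) {
    bad <- setdiff(flags, c("pul", "cazyme"))
    if (length(bad))
        stop("unknown flag name(s): ", paste(bad, collapse = ", "))
    a <- annotations(ann)
    carry <- rep(FALSE, nrow(a))
    if ("pul" %in% flags) carry <- carry | !is.na(a$pul_id)
    if ("cazyme" %in% flags) carry <- carry | a$cazyme_flag
    hit <- intersect(sig_genes, a$locus_tag[carry])
    list(count = length(hit), genes = sort(hit))
}
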