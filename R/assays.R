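#' Amplicon length from convergent primer coordinates
#'
#' Length of the PCR product defined by a forward primer start and the
#' 3' end of a convergent reverse primer, both on the template, in the
#' half-open convention: `length = r_end - f_start`.
#'
#' @param f_start Forward primer start (0-based).
#' @param r_end Reverse primer 3'-end position (one past the last
#'   amplified base).
#' @return Amplicon length in bp (> 0); divergent primers
#'   (`r_end <= f_start`) are an error.
#' @export
ampliconSize <- function(f_start, r_end) {
    if (r_end <= f_start)
        stop("divergent primers: reverse 3' end (", r_end,
             ") not downstream of forward start (", f_start, ")")
    as.integer(r_end - f_start)
}

#' Restriction fragment lengths of a digested amplicon
#'
#' Fragments are the consecutive differences of `{0, sorted offsets,
#' length}`; they always sum to the amplicon length.
#'
#' @param amplicon_length Amplicon length in bp.
#' @param cut_offsets Cut positions in bp from the amplicon start,
#'   strictly inside `(0, amplicon_length)`.
#' @return Integer vector of fragment lengths, sorted decreasing.
#' @export
digestFragments <- function(amplicon_length, cut_offsets = integer()) {
    if (length(cut_offsets) &&
        (any(cut_offsets <= 0) || any(cut_offsets >= amplicon_length)))
        stop("cut offsets must lie strictly inside the amplicon (0, ",
             amplicon_length, ")")
    bounds <- c(0L, sort(as.integer(cut_offsets)),
                as.integer(amplicon_length))
    sort(diff(bounds), decreasing = TRUE)
}

#' Locate restriction sites in an amplicon sequence
#'
#' Exact string match of an enzyme recognition site (default CCGG for
#' HpaII) in a template; returns 0-based offsets of the site start,
#' usable as `cut_offsets` in [digestFragments()] after adding the
#' enzyme's cut position within the site (1 for HpaII, C^CGG).
#'
#' @param sequence Character or [Biostrings::DNAString] amplicon
#'   sequence.
#' @param site Recognition sequence.
#' @param cut_at Cut position within the site (bp after site start).
#' @return Integer vector of cut offsets from the amplicon start.
#' @export
findCutOffsets <- function(sequence, site = "CCGG", cut_at = 1L) {
    s <- as.character(sequence)
    hits <- gregexpr(site, s, fixed = TRUE)[[1]]
    if (hits[1] == -1L) return(integer(0))
    as.integer(hits) - 1L + as.integer(cut_at)
}

#' Quantify promoter orientation fractions from digest band intensities
#'
#' An invertible promoter yields distinct restriction patterns in its ON
#' and OFF orientations.  Each observed band is matched (within
#' `tolerance_bp`) to the expected ON or OFF fragment sizes; matched
#' intensities are summed per orientation and
#' `f_on = I_on / (I_on + I_off)`, `f_off = 1 - f_on`.  A band matching
#' both patterns, or expected patterns sharing a fragment size within
#' tolerance, is an error (the patterns must be distinguishable).
#'
#' @param fragment_bp,intensity Observed band sizes and intensities.
#' @param on_pattern,off_pattern Expected fragment sizes per orientation.
#' @param tolerance_bp Size-matching tolerance.
#' @return List with `f_on` and `f_off` (`f_on + f_off == 1`).
#' @export
orientationFractions <- function(fragment_bp, intensity, on_pattern,
                                 off_pattern, tolerance_bp = 10) {
    near <- function(x, pat) vapply(x, function(v)
        any(abs(v - pat) <= tolerance_bp), logical(1))
    shared <- outer(on_pattern, off_pattern,
                    function(a, b) abs(a - b) <= tolerance_bp)
    if (any(shared))
        stop("ON and OFF patterns share fragment size(s) within tolerance: ",
             paste(on_pattern[row(shared)[shared]], collapse = ", "))
    is_on <- near(fragment_bp, on_pattern)
    is_off <- near(fragment_bp, off_pattern)
    both <- is_on & is_off
    if (any(both))
        stop("fragment(s) match both patterns: ",
             paste(fragment_bp[both], collapse = ", "))
    i_on <- sum(intensity[is_on])
    i_off <- sum(intensity[is_off])
    if (i_on + i_off <= 0)
        stop("no observed intensity matches either pattern")
    f_on <- i_on / (i_on + i_off)
    list(f_on = f_on, f_off = 1 - f_on)
}
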