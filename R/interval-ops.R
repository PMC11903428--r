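## Interval primitives. Semantics fixed once for the whole package:
## 0-based half-open coordinates at file boundaries, >= 1 shared base means
## overlap, strand is ignored everywhere except feature annotation.

.assertWellFormed <- function(x) {
    if (length(x) > 0L && any(width(x) < 1L))
        stop("malformed interval: start >= end (zero or negative width)")
    invisible(x)
}

#' Merge intervals into their union
#'
#' Collapses a set of genomic intervals into sorted, pairwise-disjoint
#' intervals covering exactly the same bases (the operation applied to the
#' two replicates' validated peaks when forming a combined peak set).
#'
#' @param x a \code{GRanges} (or \linkS4class{PeakSet}).
#' @param mergeBookended if TRUE (default, the merge-tool convention)
#'   abutting intervals (end of one equals start of the next in half-open
#'   coordinates) are joined as well.
#' @return a \code{GRanges}, sorted and pairwise non-overlapping.
#' @examples
#' gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(11, 16), c(20, 30)))
#' mergeIntervals(gr)
#' @export
mergeIntervals <- function(x, mergeBookended = TRUE) {
    stopifnot(is(x, "GRanges"))
    .assertWellFormed(x)
    reduce(granges(x), min.gapwidth = if (mergeBookended) 1L else 0L,
           ignore.strand = TRUE)
}

#' Does each query interval overlap any target peak?
#'
#' Overlap means at least one shared base; strand is ignored; abutting
#' half-open intervals do not overlap.
#'
#' @param query a \code{GRanges}.
#' @param target a \code{GRanges} or \linkS4class{PeakSet}.
#' @return logical vector along \code{query}.
#' @export
overlapsPeaks <- function(query, target) {
    stopifnot(is(query, "GRanges"), is(target, "GRanges"))
    overlapsAny(query, target, ignore.strand = TRUE)
}

#' Total number of distinct covered bases
#'
#' Invariant to input order and duplication; the numerator of genome
#' coverage percentages.
#'
#' @param x a \code{GRanges} (or \linkS4class{PeakSet}).
#' @return covered bases (bp), a single number.
#' @export
unionLength <- function(x) {
    stopifnot(is(x, "GRanges"))
    .assertWellFormed(x)
    sum(as.numeric(width(reduce(granges(x), ignore.strand = TRUE))))
}

#' Check intervals against a genome
#'
#' @param x a \code{GRanges}.
#' @param genome a \code{Seqinfo}.
#' @return \code{x}, invisibly; errors when a range lies on an unknown
#'   chromosome or extends past its end.
#' @export
checkAgainstGenome <- function(x, genome) {
    stopifnot(is(genome, "Seqinfo"))
    sl <- seqlengths(genome)
    chr <- as.character(seqnames(x))
    unknown <- !chr %in% names(sl)
    if (any(unknown))
        stop(sprintf("chromosome(s) not in genome: %s",
            paste(unique(chr[unknown]), collapse = ", ")))
    if (any(end(x) > sl[chr] | start(x) < 1L))
        stop("interval out of chromosome bounds")
    invisible(x)
}
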