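## Replicate validation: fold-enrichment filtering, reciprocal
## intersection with the other replicate's full call set, and merging into
## a combined peak set. FDR is not re-checked here: membership in a
## replicate's call set certifies the FDR cutoff that was applied at
## calling time.

.feThreshold <- function(style, cfg) {
    if (style == "narrow") cfg@feNarrow else cfg@feBroad
}

#' Filter peaks by fold enrichment
#'
#' Retains peaks whose FE over input is strictly greater than the
#' threshold (2.0 for narrow marks, 1.5 for broad marks, by convention);
#' order is preserved.
#'
#' @param peaks a \linkS4class{PeakSet} whose peaks carry
#'   \code{foldEnrichment}.
#' @param threshold strict lower FE bound.
#' @return the filtered \linkS4class{PeakSet}.
#' @export
filterByFoldEnrichment <- function(peaks, threshold) {
    stopifnot(is(peaks, "PeakSet"))
    if (length(peaks) == 0L) return(peaks)
    fe <- mcols(peaks)$foldEnrichment
    if (is.null(fe) || anyNA(fe))
        stop("every peak must carry a foldEnrichment value")
    peaks[fe > threshold]
}

#' Validate FE-filtered peaks against the other replicate
#'
#' One direction of reciprocal validation: keeps the whole record of every
#' FE-filtered peak that shares >= 1 base with any peak of the other
#' replicate's complete call set (coordinates are not clipped).
#'
#' @param filtered FE-thresholded \linkS4class{PeakSet} of one replicate.
#' @param otherAll the complete call set of the other replicate.
#' @return the validated subset of \code{filtered}.
#' @export
validateAgainstReplicate <- function(filtered, otherAll) {
    stopifnot(is(filtered, "PeakSet"), is(otherAll, "PeakSet"))
    .checkPairing(filtered, otherAll)
    filtered[overlapsPeaks(filtered, otherAll)]
}

.checkPairing <- function(a, b) {
    if (nzchar(a@mark) && nzchar(b@mark) && a@mark != b@mark)
        stop(sprintf("mark mismatch between replicates: '%s' vs '%s'",
            a@mark, b@mark))
    if (nzchar(a@tissue) && nzchar(b@tissue) && a@tissue != b@tissue)
        stop(sprintf("tissue mismatch between replicates: '%s' vs '%s'",
            a@tissue, b@tissue))
    invisible(TRUE)
}

#' Build the replicate-validated combined peak set
#'
#' FE-filtered peaks of each replicate are intersected with all called
#' peaks of the other replicate; the validated peaks of both directions
#' are merged. Every combined peak therefore passed the caller's FDR
#' cutoff in both replicates and exceeded the FE threshold (narrow 2.0 /
#' broad 1.5, strict) in at least one. Combined peaks carry no scores,
#' only provenance counts (\code{nRecordsA}/\code{nRecordsB}: validated
#' records of each replicate merged into the peak).
#'
#' @param repA,repB the two replicates' \linkS4class{PeakSet}s (same mark
#'   and tissue).
#' @param config a \linkS4class{ValidationConfig}.
#' @return a \linkS4class{PeakSet} with replicate label "combined".
#' @examples
#' gr <- function(s, e, fe) GenomicRanges::GRanges("c1",
#'     IRanges::IRanges(s, e), foldEnrichment = fe)
#' a <- PeakSet(gr(101, 200, 2.5), "H3K27ac", "liver", "rep1")
#' b <- PeakSet(gr(151, 300, 1.2), "H3K27ac", "liver", "rep2")
#' combineReplicates(a, b)   # retained: FE passes in one replicate
#' @export
combineReplicates <- function(repA, repB, config = validationConfig()) {
    stopifnot(is(repA, "PeakSet"), is(repB, "PeakSet"),
        is(config, "ValidationConfig"))
    .checkPairing(repA, repB)
    if (repA@callerStyle != repB@callerStyle)
        stop("replicates must share a caller style")
    style <- repA@callerStyle
    mk <- if (nzchar(repA@mark)) repA@mark else repB@mark
    ts <- if (nzchar(repA@tissue)) repA@tissue else repB@tissue
    empty <- function() PeakSet(GRanges(seqinfo = seqinfo(repA)), mk, ts,
        "combined", style)
    if (length(repA) == 0L || length(repB) == 0L) {
        warning("empty replicate call set; combined set is empty")
        return(empty())
    }
    thr <- .feThreshold(style, config)
    vA <- validateAgainstReplicate(filterByFoldEnrichment(repA, thr), repB)
    vB <- validateAgainstReplicate(filterByFoldEnrichment(repB, thr), repA)
    recA <- granges(vA)
    recB <- granges(vB)
    if (config@clipToOverlap) {
        recA <- intersect(recA, granges(repB), ignore.strand = TRUE)
        recB <- intersect(recB, granges(repA), ignore.strand = TRUE)
    }
    merged <- mergeIntervals(c(recA, recB), config@mergeBookended)
    mcols(merged)$nRecordsA <- countOverlaps(merged, recA,
        ignore.strand = TRUE)
    mcols(merged)$nRecordsB <- countOverlaps(merged, recB,
        ignore.strand = TRUE)
    PeakSet(merged, mk, ts, "combined", style)
}
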