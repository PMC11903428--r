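## Quality and summary metrics: FRiP, genome coverage, effective genome
## fraction, peak-width order statistics, caller-overlap fraction and the
## narrow-in-broad nesting profile.

#' Fraction of Reads in Peaks (FRiP)
#'
#' Share of usable fragments overlapping (>= 1 bp) at least one peak;
#' each fragment counts at most once however many peaks it touches.
#'
#' @param fragments a non-empty \linkS4class{FragmentSet}.
#' @param peaks a \linkS4class{PeakSet} (or \code{GRanges}).
#' @return fraction in [0, 1].
#' @export
frip <- function(fragments, peaks) {
    stopifnot(is(fragments, "FragmentSet"))
    if (length(fragments) == 0L)
        stop("FRiP is undefined for an empty fragment set")
    if (length(peaks) == 0L) return(0)
    mean(overlapsPeaks(fragments, peaks))
}

#' Percent of the genome covered by peaks
#'
#' 100 x distinct covered bases / total genome length; invariant to peak
#' order and duplication.
#'
#' @param peaks a \linkS4class{PeakSet} (or \code{GRanges}).
#' @param genome a \code{Seqinfo}.
#' @return percent in [0, 100].
#' @export
genomeCoveragePct <- function(peaks, genome) {
    stopifnot(is(genome, "Seqinfo"))
    100 * unionLength(peaks) / sum(as.numeric(seqlengths(genome)))
}

#' Effective genome fraction from merged input samples
#'
#' Fraction of the genome covered by the union of all input-control
#' fragment sets — the mappable-genome proxy fed to peak callers.
#'
#' @param inputs list of \linkS4class{FragmentSet}s (>= 1).
#' @param genome a \code{Seqinfo}.
#' @return fraction in [0, 1].
#' @export
effectiveGenomeFraction <- function(inputs, genome) {
    stopifnot(is.list(inputs), length(inputs) >= 1L, is(genome, "Seqinfo"))
    all <- do.call(c, unname(lapply(inputs, granges)))
    unionLength(all) / sum(as.numeric(seqlengths(genome)))
}

#' Peak width order statistics
#'
#' @param peaks a non-empty \linkS4class{PeakSet}.
#' @return named numeric: mean, median, min, max width in bp (median of an
#'   even count is the mean of the central pair).
#' @export
widthStats <- function(peaks) {
    stopifnot(is(peaks, "GRanges"))
    if (length(peaks) == 0L)
        stop("width statistics are undefined for an empty peak set")
    w <- width(peaks)
    c(mean = mean(w), median = median(w), min = min(w), max = max(w))
}

#' Fraction of peaks in a overlapping peaks in b
#'
#' Asymmetric by design: the share of \code{a}'s peaks sharing >= 1 base
#' with any peak of \code{b} (e.g. narrow-caller peaks overlapping
#' island-caller peaks).
#'
#' @param a a non-empty \linkS4class{PeakSet}.
#' @param b a \linkS4class{PeakSet}.
#' @return fraction in [0, 1].
#' @export
overlapFraction <- function(a, b) {
    stopifnot(is(a, "GRanges"), is(b, "GRanges"))
    if (length(a) == 0L)
        stop("overlap fraction is undefined for an empty query set")
    mean(overlapsPeaks(a, b))
}

#' Narrow-peaks-per-broad-peak nesting profile
#'
#' For each broad/island peak, the number of narrow peaks fully contained
#' in it (the smoothing signature where one large island spans many
#' consecutive narrow peaks).
#'
#' @param narrow,broad \linkS4class{PeakSet}s.
#' @return integer vector along \code{broad}: contained-narrow-peak counts
#'   (tabulate for a histogram).
#' @export
nestingProfile <- function(narrow, broad) {
    stopifnot(is(narrow, "GRanges"), is(broad, "GRanges"))
    hits <- findOverlaps(granges(narrow), granges(broad), type = "within",
        ignore.strand = TRUE)
    tabulate(subjectHits(hits), nbins = length(broad))
}

#' Per-mark summary row
#'
#' Bundles the peak-level summary of a combined set: peak count, width
#' statistics, genome coverage percent (1 dp convention in reports) and
#' FRiP per replicate fragment set.
#'
#' @param peaks a combined \linkS4class{PeakSet}.
#' @param fragmentsByReplicate named list of \linkS4class{FragmentSet}s.
#' @param genome a \code{Seqinfo}.
#' @return one-row \code{data.frame} with columns mark, tissue, nPeaks,
#'   meanWidth, medianWidth, minWidth, maxWidth, coveragePct and one
#'   \code{frip.<replicate>} column per fragment set.
#' @export
markSummary <- function(peaks, fragmentsByReplicate, genome) {
    stopifnot(is(peaks, "PeakSet"))
    ws <- if (length(peaks) > 0L) widthStats(peaks) else
        c(mean = NA_real_, median = NA_real_, min = NA_real_,
          max = NA_real_)
    row <- data.frame(
        mark = peaks@mark, tissue = peaks@tissue,
        callerStyle = peaks@callerStyle,
        nPeaks = length(peaks),
        meanWidth = unname(ws["mean"]), medianWidth = unname(ws["median"]),
        minWidth = unname(ws["min"]), maxWidth = unname(ws["max"]),
        coveragePct = genomeCoveragePct(peaks, genome),
        stringsAsFactors = FALSE)
    for (rep in names(fragmentsByReplicate))
        row[[paste0("frip.", rep)]] <- frip(fragmentsByReplicate[[rep]],
            peaks)
    row
}
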