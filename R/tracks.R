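## Signal-track construction: fixed-bin fragment coverage, SES (signal
## extraction scaling) of the input control, input subtraction with
## negative values retained, and unweighted replicate averaging.

#' Bin fragment coverage on a fixed grid
#'
#' \code{values[i]} counts the fragments overlapping bin \code{i} by at
#' least one base; the last bin of each chromosome is truncated at the
#' chromosome end.
#'
#' @param fragments a \linkS4class{FragmentSet}.
#' @param genome a \code{Seqinfo}.
#' @param binSize bin width in bp (default 50, a common track
#'   resolution).
#' @return a \linkS4class{BinnedCoverage}.
#' @export
binCoverage <- function(fragments, genome, binSize = 50L) {
    stopifnot(is(fragments, "GRanges"), is(genome, "Seqinfo"))
    binSize <- as.integer(binSize)
    if (binSize < 1L) stop("binSize must be >= 1")
    sl <- seqlengths(genome)
    frag <- granges(fragments)
    values <- lapply(names(sl), function(chr) {
        nb <- ceiling(sl[[chr]] / binSize)
        bins <- GRanges(chr, IRanges(
            start = (seq_len(nb) - 1L) * binSize + 1L,
            end = pmin(seq_len(nb) * binSize, sl[[chr]])))
        as.numeric(suppressWarnings(
            countOverlaps(bins, frag, ignore.strand = TRUE)))
    })
    names(values) <- names(sl)
    new("BinnedCoverage", seqinfo = genome, binSize = binSize,
        values = values)
}

.checkGrid <- function(a, b) {
    if (a@binSize != b@binSize ||
        !identical(lengths(a@values), lengths(b@values)) ||
        !identical(names(a@values), names(b@values)))
        stop("coverage grids do not match (binSize/chromosomes/bins)")
    invisible(TRUE)
}

.flatten <- function(cov) unlist(cov@values, use.names = FALSE)

#' SES scale factor for an input control
#'
#' Signal extraction scaling: bins are ordered by ascending sample
#' signal (ties broken by bin index); along that ordering the cumulative
#' fractions of total sample and total control signal are compared, and
#' the scale factor is the ratio of cumulative sample to cumulative
#' control counts at the point where (control fraction - sample fraction)
#' is maximal. Candidate points are restricted to those with positive
#' cumulative mass in both tracks (on sparse grids the unrestricted
#' maximum can sit inside the zero-sample prefix, where the ratio
#' degenerates) and the last maximizer is taken on ties, so identical
#' sample and control give exactly 1. The control track is multiplied by
#' this factor before subtraction.
#'
#' @param sample,control \linkS4class{BinnedCoverage} on the same grid;
#'   neither may be all-zero.
#' @return a finite positive ratio.
#' @export
sesScaleFactor <- function(sample, control) {
    stopifnot(is(sample, "BinnedCoverage"), is(control, "BinnedCoverage"))
    .checkGrid(sample, control)
    x <- .flatten(sample)
    y <- .flatten(control)
    if (all(x == 0)) stop("all-zero sample signal: SES undefined")
    if (all(y == 0)) stop("all-zero control signal: SES undefined")
    ord <- order(x)                       # stable: ties keep bin order
    cs <- cumsum(x[ord])
    cc <- cumsum(y[ord])
    d <- cc / cc[length(cc)] - cs / cs[length(cs)]
    ## candidate split points need positive cumulative mass in both
    ## tracks, otherwise the ratio degenerates on sparse grids; the last
    ## maximizer is taken on ties, so identical tracks give exactly 1
    valid <- which(cs > 0 & cc > 0)
    k <- valid[max(which(d[valid] == max(d[valid])))]
    factor <- cs[k] / cc[k]
    if (!is.finite(factor) || factor <= 0)
        stop("degenerate SES scale factor")
    factor
}

#' Subtract scaled input from a sample track
#'
#' Elementwise \code{sample - factor * control}; negative values are
#' retained (loci where the scaled input exceeds the sample are rendered,
#' not clipped).
#'
#' @param sample,control \linkS4class{BinnedCoverage} on the same grid.
#' @param factor the SES scale factor (default: computed from the pair).
#' @return a \linkS4class{BinnedCoverage}.
#' @export
subtractInput <- function(sample, control,
                          factor = sesScaleFactor(sample, control)) {
    .checkGrid(sample, control)
    values <- Map(function(s, c) s - factor * c, sample@values,
        control@values)
    new("BinnedCoverage", seqinfo = sample@seqinfo,
        binSize = sample@binSize, values = values)
}

#' Average two replicate tracks
#'
#' Unweighted elementwise mean of exactly two biological replicates.
#'
#' @param a,b \linkS4class{BinnedCoverage} on the same grid.
#' @return a \linkS4class{BinnedCoverage}.
#' @export
averageReplicates <- function(a, b) {
    stopifnot(is(a, "BinnedCoverage"), is(b, "BinnedCoverage"))
    .checkGrid(a, b)
    values <- Map(function(x, y) (x + y) / 2, a@values, b@values)
    new("BinnedCoverage", seqinfo = a@seqinfo, binSize = a@binSize,
        values = values)
}

#' Build a combined signal track for one sample
#'
#' The full chain: bin both replicates and their input(s), SES-scale and
#' subtract the input within each replicate, then average the two
#' input-subtracted replicate tracks.
#'
#' @param fragA,fragB replicate \linkS4class{FragmentSet}s.
#' @param inputA,inputB matching input-control fragment sets (pass the
#'   same set twice for a shared input).
#' @param genome a \code{Seqinfo}.
#' @param binSize bin width in bp.
#' @return a \linkS4class{BinnedCoverage} combined track.
#' @export
combinedSignalTrack <- function(fragA, fragB, inputA, inputB, genome,
                                binSize = 50L) {
    cA <- binCoverage(fragA, genome, binSize)
    cB <- binCoverage(fragB, genome, binSize)
    iA <- binCoverage(inputA, genome, binSize)
    iB <- binCoverage(inputB, genome, binSize)
    averageReplicates(subtractInput(cA, iA), subtractInput(cB, iB))
}
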