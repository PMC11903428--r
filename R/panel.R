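## Tissue-panel comparison: tissue-unique peaks across a multi-tissue
## panel of combined peak sets, plus the read-depth correlation
## diagnostics.

#' Peaks unique to one tissue within a panel
#'
#' A tissue's peak is unique when it shares no base with any peak of the
#' same mark in any other panel tissue (1 bp of overlap already makes a
#' peak "shared"; no reciprocal-fraction requirement).
#'
#' @param panel a \linkS4class{TissuePanel}.
#' @param tissue tissue name.
#' @return the tissue's unique-peak \linkS4class{PeakSet}.
#' @export
tissueUniquePeaks <- function(panel, tissue) {
    stopifnot(is(panel, "TissuePanel"))
    ps <- panelPeaks(panel, tissue)
    others <- panel@peaksets[setdiff(names(panel@peaksets), tissue)]
    if (length(others) == 0L) return(ps)
    othersGr <- do.call(c, unname(lapply(others, granges)))
    ps[!overlapsPeaks(ps, othersGr)]
}

#' Pearson product-moment correlation
#'
#' Sample Pearson correlation with the preconditions the panel
#' diagnostics assume: equal length >= 3 and both vectors non-constant.
#'
#' @param x,y numeric vectors.
#' @return correlation in [-1, 1].
#' @export
pearsonR <- function(x, y) {
    if (length(x) != length(y))
        stop("x and y must have equal length")
    if (length(x) < 3L)
        stop("correlation needs at least 3 observations")
    if (anyNA(x) || anyNA(y))
        stop("correlation inputs must not contain NA")
    if (isTRUE(all.equal(stats::var(x), 0)) ||
        isTRUE(all.equal(stats::var(y), 0)))
        stop("correlation is undefined for a constant vector")
    cor(x, y, method = "pearson")
}

#' Panel-wide uniqueness report
#'
#' Per tissue: total combined peaks, tissue-unique peaks and percent
#' unique (reported at 1 dp); panel-wide: Pearson correlation of total
#' vs unique peak counts, of minimum usable reads vs total peak counts
#' (when read counts are attached), and the shared fraction
#' \code{1 - sum(unique)/sum(total)}.
#'
#' @param panel a \linkS4class{TissuePanel}.
#' @return a list with \code{perTissue} (data.frame: tissue, totalPeaks,
#'   uniquePeaks, pctUnique), \code{rTotalUnique}, \code{rReadsTotal}
#'   (NA when no read counts), and \code{sharedFraction}.
#' @export
uniquenessReport <- function(panel) {
    stopifnot(is(panel, "TissuePanel"))
    tissues <- names(panel@peaksets)
    total <- vapply(tissues, function(t) length(panelPeaks(panel, t)),
        integer(1L))
    uniq <- vapply(tissues, function(t) length(tissueUniquePeaks(panel, t)),
        integer(1L))
    perTissue <- data.frame(
        tissue = tissues,
        totalPeaks = unname(total),
        uniquePeaks = unname(uniq),
        pctUnique = round(100 * unname(uniq) / pmax(unname(total), 1L), 1L),
        stringsAsFactors = FALSE)
    rTotalUnique <- tryCatch(pearsonR(as.numeric(total), as.numeric(uniq)),
        error = function(e) NA_real_)
    rReadsTotal <- NA_real_
    if (length(panel@usableReads) > 0L)
        rReadsTotal <- tryCatch(
            pearsonR(as.numeric(panel@usableReads[tissues]),
                     as.numeric(total)),
            error = function(e) NA_real_)
    list(perTissue = perTissue,
         rTotalUnique = rTotalUnique,
         rReadsTotal = rReadsTotal,
         sharedFraction = 1 - sum(uniq) / max(sum(total), 1L))
}
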