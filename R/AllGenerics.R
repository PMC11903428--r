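#' @name accessors
#' @title Accessors for ChIPpanel classes
#' @param x an object.
#' @return the slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("mark", function(x) standardGeneric("mark"))
#' @rdname accessors
#' @export
setGeneric("tissue", function(x) standardGeneric("tissue"))
#' @rdname accessors
#' @export
setGeneric("replicateLabel", function(x) standardGeneric("replicateLabel"))
#' @rdname accessors
#' @export
setGeneric("callerStyle", function(x) standardGeneric("callerStyle"))
#' @rdname accessors
#' @export
setGeneric("sampleName", function(x) standardGeneric("sampleName"))
#' @rdname accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))
#' @rdname accessors
#' @export
setGeneric("coverageValues", function(x) standardGeneric("coverageValues"))
#' @rdname accessors
#' @export
setGeneric("panelTissues", function(x) standardGeneric("panelTissues"))
#' @rdname accessors
#' @export
setGeneric("usableReads", function(x) standardGeneric("usableReads"))
#' @rdname accessors
#' @export
setGeneric("transcripts", function(x) standardGeneric("transcripts"))
#' @rdname accessors
#' @export
setGeneric("exonsBy", function(x) standardGeneric("exonsBy"))

#' @rdname accessors
#' @export
setMethod("mark", "PeakSet", function(x) x@mark)
#' @rdname accessors
#' @export
setMethod("mark", "TissuePanel", function(x) x@mark)
#' @rdname accessors
#' @export
setMethod("tissue", "PeakSet", function(x) x@tissue)
#' @rdname accessors
#' @export
setMethod("replicateLabel", "PeakSet", function(x) x@replicate)
#' @rdname accessors
#' @export
setMethod("callerStyle", "PeakSet", function(x) x@callerStyle)
#' @rdname accessors
#' @export
setMethod("callerStyle", "TissuePanel", function(x) x@callerStyle)
#' @rdname accessors
#' @export
setMethod("sampleName", "FragmentSet", function(x) x@sample)
#' @rdname accessors
#' @export
setMethod("binSize", "BinnedCoverage", function(x) x@binSize)
#' @rdname accessors
#' @export
setMethod("coverageValues", "BinnedCoverage", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("panelTissues", "TissuePanel", function(x) names(x@peaksets))
#' @rdname accessors
#' @export
setMethod("usableReads", "TissuePanel", function(x) x@usableReads)
#' @rdname accessors
#' @export
setMethod("transcripts", "GeneModels", function(x) x@transcripts)
#' @rdname accessors
#' @export
setMethod("exonsBy", "GeneModels", function(x) x@exons)

#' Extract a panel member peak set
#'
#' @param x a \linkS4class{TissuePanel}.
#' @param tissue tissue name.
#' @return the tissue's combined \linkS4class{PeakSet}.
#' @export
panelPeaks <- function(x, tissue) {
    stopifnot(is(x, "TissuePanel"))
    if (!tissue %in% names(x@peaksets))
        stop(sprintf("unknown tissue '%s' in panel", tissue))
    x@peaksets[[tissue]]
}

setMethod("show", "PeakSet", function(object) {
    cat(sprintf("PeakSet: %d peaks [%s%s%s, %s]\n", length(object),
        if (nzchar(object@mark)) object@mark else "<mark unset>",
        if (nzchar(object@tissue)) paste0(", ", object@tissue) else "",
        if (nzchar(object@replicate)) paste0(", ", object@replicate) else "",
        object@callerStyle))
    callNextMethod()
})

setMethod("show", "FragmentSet", function(object) {
    cat(sprintf("FragmentSet: %d fragments [sample '%s']\n",
        length(object), object@sample))
    callNextMethod()
})

setMethod("show", "GeneModels", function(object) {
    cat(sprintf("GeneModels: %d transcripts, %d genes\n",
        length(object@transcripts),
        length(unique(mcols(object@transcripts)$geneId)))) })

setMethod("show", "FeatureIndex", function(object) {
    cat(sprintf(
        "FeatureIndex: %d transcripts (promoter +/-%d bp, downstream %d bp)\n",
        length(object@promoters), object@promoterWindow,
        object@downstreamWindow)) })

setMethod("show", "BinnedCoverage", function(object) {
    cat(sprintf("BinnedCoverage: %d chromosomes, bin %d bp, %d bins\n",
        length(object@values), object@binSize,
        sum(lengths(object@values)))) })

setMethod("show", "TissuePanel", function(object) {
    cat(sprintf("TissuePanel: mark %s (%s), %d tissues: %s\n",
        object@mark, object@callerStyle, length(object@peaksets),
        paste(names(object@peaksets), collapse = ", "))) })

setMethod("show", "ValidationConfig", function(object) {
    cat(sprintf(
        "ValidationConfig: FE > %.2f (narrow) / %.2f (broad); %s; %s\n",
        object@feNarrow, object@feBroad,
        if (object@mergeBookended) "merge bookended" else "keep bookended",
        if (object@clipToOverlap) "clip to overlap" else "whole records")) })
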