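## Central S4 classes. Coordinates are BED-style 0-based half-open at every
## file boundary and 1-based closed GRanges internally; converters live in
## the io readers/writers only.

VALID_MARKS <- c("H3K4me1", "H3K4me3", "H3K27ac", "H3K27me3")
CALLER_STYLES <- c("narrow", "broad", "island")

#' PeakSet: a sorted collection of ChIP-seq peaks
#'
#' Extends \linkS4class{GRanges}. Metadata columns (all optional except for
#' stages that require them): \code{name}, \code{score},
#' \code{foldEnrichment} (FE over the input control), \code{neglog10P},
#' \code{neglog10Q} (the call's FDR on -log10 scale), and
#' \code{summitOffset} (0-based offset of the summit within the peak;
#' \code{NA} for broad/island peaks without summits).
#'
#' @slot mark histone mark label, one of H3K4me1, H3K4me3, H3K27ac,
#'   H3K27me3 (or "" when unset).
#' @slot tissue tissue label.
#' @slot replicate replicate label, or "combined" for replicate-validated
#'   merged sets.
#' @slot callerStyle one of "narrow", "broad", "island".
#' @export
setClass("PeakSet",
    contains = "GRanges",
    representation(
        mark = "character",
        tissue = "character",
        replicate = "character",
        callerStyle = "character"
    ),
    prototype(mark = "", tissue = "", replicate = "", callerStyle = "narrow")
)

setValidity("PeakSet", function(object) {
    msg <- character()
    for (s in c("mark", "tissue", "replicate", "callerStyle")) {
        if (length(slot(object, s)) != 1L)
            msg <- c(msg, sprintf("slot '%s' must be a single string", s))
    }
    if (length(object@mark) == 1L && nzchar(object@mark) &&
        !object@mark %in% VALID_MARKS)
        msg <- c(msg, sprintf("unknown mark '%s'", object@mark))
    if (length(object@callerStyle) == 1L &&
        !object@callerStyle %in% CALLER_STYLES)
        msg <- c(msg, sprintf("callerStyle must be one of %s",
            paste(CALLER_STYLES, collapse = "/")))
    if (length(object) > 0L) {
        if (any(width(object) < 1L))
            msg <- c(msg, "malformed interval: all peaks must have width >= 1")
        mc <- mcols(object)
        if ("foldEnrichment" %in% names(mc)) {
            fe <- mc$foldEnrichment
            if (any(!is.na(fe) & fe < 0))
                msg <- c(msg, "foldEnrichment must be >= 0")
        }
        if ("summitOffset" %in% names(mc)) {
            so <- mc$summitOffset
            bad <- !is.na(so) & (so < 0L | so >= width(object))
            if (any(bad))
                msg <- c(msg, "summitOffset must satisfy 0 <= offset < width")
        }
        if (is.unsorted(order(as.integer(seqnames(object)), start(object),
                              end(object))))
            msg <- c(msg, "peaks must be sorted by (chrom, start, end)")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a PeakSet
#'
#' @param gr a \code{GRanges} (metadata columns are kept; peaks are sorted
#'   by chromosome, start, end on construction).
#' @param mark,tissue,replicate labels; see \linkS4class{PeakSet}.
#' @param callerStyle "narrow", "broad" or "island".
#' @return a \linkS4class{PeakSet}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 600),
#'     foldEnrichment = 5.2)
#' PeakSet(gr, mark = "H3K27ac", tissue = "liver", replicate = "rep1")
#' @export
PeakSet <- function(gr = GRanges(), mark = "", tissue = "", replicate = "",
                    callerStyle = c("narrow", "broad", "island")) {
    callerStyle <- match.arg(callerStyle)
    if (length(gr) > 0L && any(width(gr) < 1L))
        stop("malformed interval: start >= end (zero or negative width)")
    o <- order(as.integer(seqnames(gr)), start(gr), end(gr))
    new("PeakSet", gr[o], mark = mark, tissue = tissue,
        replicate = replicate, callerStyle = callerStyle)
}

#' FragmentSet: usable sequencing fragments as intervals
#'
#' Extends \linkS4class{GRanges}; one range per usable fragment (the
#' deduplicated, quality-filtered read-pair proxy that drives FRiP,
#' effective genome fraction and coverage tracks).
#'
#' @slot sample sample label.
#' @export
setClass("FragmentSet",
    contains = "GRanges",
    representation(sample = "character"),
    prototype(sample = "")
)

setValidity("FragmentSet", function(object) {
    msg <- character()
    if (length(object@sample) != 1L)
        msg <- c(msg, "slot 'sample' must be a single string")
    if (length(object) > 0L && any(width(object) < 1L))
        msg <- c(msg, "malformed interval: all fragments must have width >= 1")
    if (length(msg)) msg else TRUE
})

#' Construct a FragmentSet
#'
#' @param gr a \code{GRanges} of fragment intervals.
#' @param sample sample label.
#' @return a \linkS4class{FragmentSet}.
#' @export
FragmentSet <- function(gr = GRanges(), sample = "") {
    o <- order(as.integer(seqnames(gr)), start(gr), end(gr))
    new("FragmentSet", gr[o], sample = sample)
}

#' GeneModels: transcript models with exon structure
#'
#' @slot transcripts \code{GRanges} of transcript spans with metadata
#'   columns \code{txId} and \code{geneId}; strand is + or -.
#' @slot exons \code{GRangesList} of exons, parallel to and named after
#'   \code{transcripts$txId}; exons are sorted, non-overlapping and
#'   contained in the transcript span.
#' @export
setClass("GeneModels",
    representation(transcripts = "GRanges", exons = "GRangesList"))

setValidity("GeneModels", function(object) {
    tx <- object@transcripts
    ex <- object@exons
    msg <- character()
    if (length(tx) != length(ex))
        msg <- c(msg, "transcripts and exons must be parallel")
    if (length(tx) > 0L &&
        !all(c("txId", "geneId") %in% names(mcols(tx))))
        msg <- c(msg, "transcripts need txId and geneId metadata columns")
    if (length(tx) > 0L) {
        if (any(!as.character(strand(tx)) %in% c("+", "-")))
            msg <- c(msg, "every transcript must be stranded (+ or -)")
        for (i in seq_along(tx)) {
            ei <- ex[[i]]
            if (length(ei) == 0L) {
                msg <- c(msg, sprintf("transcript '%s' has no exons",
                    mcols(tx)$txId[i]))
                next
            }
            if (any(start(ei) < start(tx)[i]) || any(end(ei) > end(tx)[i]))
                msg <- c(msg, sprintf(
                    "exon outside transcript span for '%s'", mcols(tx)$txId[i]))
            if (length(ei) > 1L) {
                if (is.unsorted(start(ei)) ||
                    any(start(ei)[-1L] <= end(ei)[-length(ei)]))
                    msg <- c(msg, sprintf(
                        "exons of '%s' must be sorted and non-overlapping",
                        mcols(tx)$txId[i]))
            }
        }
    }
    if (length(msg)) head(msg, 5L) else TRUE
})

#' Construct GeneModels
#'
#' @param transcripts transcript-span \code{GRanges} with \code{txId} and
#'   \code{geneId} metadata columns.
#' @param exons \code{GRangesList} of exons parallel to transcripts.
#' @return a \linkS4class{GeneModels} object.
#' @export
GeneModels <- function(transcripts, exons) {
    names(exons) <- mcols(transcripts)$txId
    new("GeneModels", transcripts = transcripts, exons = exons)
}

#' FeatureIndex: queryable promoter/exon/intron/downstream index
#'
#' Built from \linkS4class{GeneModels} by [buildFeatureIndex()]; holds the
#' strand-aware promoter windows (TSS +/- \code{promoterWindow}) and
#' downstream windows (\code{downstreamWindow} bp past the transcript 3'
#' end), both clipped to the chromosome when a genome is attached.
#'
#' @slot models the source \linkS4class{GeneModels}.
#' @slot promoters promoter windows, parallel to the transcripts.
#' @slot downstream downstream windows, parallel to the transcripts.
#' @slot tss width-1 TSS positions, parallel to the transcripts.
#' @slot promoterWindow,downstreamWindow window half-width / width in bp.
#' @export
setClass("FeatureIndex",
    representation(
        models = "GeneModels",
        promoters = "GRanges",
        downstream = "GRanges",
        tss = "GRanges",
        promoterWindow = "integer",
        downstreamWindow = "integer"
    ))

#' BinnedCoverage: fixed-bin per-chromosome signal
#'
#' Per-chromosome numeric vectors on a fixed bin grid; raw fragment counts
#' are non-negative, but values may go negative after input subtraction
#' (loci where the scaled input exceeds the sample signal are kept, not
#' clipped).
#'
#' @slot seqinfo the genome (\code{Seqinfo}).
#' @slot binSize bin width in bp.
#' @slot values named list of per-chromosome numeric vectors; chromosome
#'   \code{c} has \code{ceiling(seqlength(c)/binSize)} bins.
#' @export
setClass("BinnedCoverage",
    representation(seqinfo = "Seqinfo", binSize = "integer", values = "list"))

setValidity("BinnedCoverage", function(object) {
    msg <- character()
    if (length(object@binSize) != 1L || object@binSize < 1L)
        msg <- c(msg, "binSize must be a single integer >= 1")
    sl <- seqlengths(object@seqinfo)
    if (!identical(sort(names(object@values)), sort(names(sl))))
        msg <- c(msg, "values must be named by the genome's chromosomes")
    else {
        expected <- ceiling(sl / object@binSize)
        got <- lengths(object@values)[names(sl)]
        if (any(got != expected))
            msg <- c(msg, "bin count must be ceiling(chrom length / binSize)")
    }
    if (length(msg)) msg else TRUE
})

#' TissuePanel: one mark's combined peak sets across tissues
#'
#' @slot mark the histone mark shared by all member peak sets.
#' @slot callerStyle caller style shared by all member peak sets.
#' @slot peaksets named list (tissue -> combined \linkS4class{PeakSet}).
#' @slot usableReads named numeric, minimum usable reads across the two
#'   biological replicates per tissue (may be empty when read counts are
#'   not supplied).
#' @export
setClass("TissuePanel",
    representation(
        mark = "character",
        callerStyle = "character",
        peaksets = "list",
        usableReads = "numeric"
    ))

setValidity("TissuePanel", function(object) {
    msg <- character()
    if (length(object@peaksets) < 2L)
        msg <- c(msg, "a panel needs >= 2 tissues")
    if (is.null(names(object@peaksets)) ||
        anyDuplicated(names(object@peaksets)))
        msg <- c(msg, "peaksets must be uniquely named by tissue")
    if (!all(vapply(object@peaksets, is, logical(1L), "PeakSet")))
        msg <- c(msg, "every panel member must be a PeakSet")
    else {
        mk <- vapply(object@peaksets, function(p) p@mark, character(1L))
        if (nzchar(object@mark) && any(nzchar(mk) & mk != object@mark))
            msg <- c(msg, "all member peak sets must share the panel's mark")
    }
    if (length(object@usableReads) > 0L &&
        !all(names(object@peaksets) %in% names(object@usableReads)))
        msg <- c(msg, "usableReads must cover every panel tissue")
    if (length(msg)) msg else TRUE
})

#' Construct a TissuePanel
#'
#' @param peaksets named list of combined \linkS4class{PeakSet}s, one per
#'   tissue.
#' @param usableReads optional named numeric: minimum usable reads across
#'   replicates per tissue (the read-depth covariate of the correlation
#'   diagnostics).
#' @param mark mark label; taken from the first peak set when omitted.
#' @param callerStyle caller style; taken from the first peak set when
#'   omitted.
#' @return a \linkS4class{TissuePanel}.
#' @export
TissuePanel <- function(peaksets, usableReads = numeric(), mark = NULL,
                        callerStyle = NULL) {
    if (is.null(mark)) mark <- peaksets[[1L]]@mark
    if (is.null(callerStyle)) callerStyle <- peaksets[[1L]]@callerStyle
    new("TissuePanel", mark = mark, callerStyle = callerStyle,
        peaksets = peaksets, usableReads = usableReads)
}

#' ValidationConfig: replicate-validation parameters
#'
#' @slot feNarrow strict fold-enrichment threshold for narrow marks
#'   (default 2.0).
#' @slot feBroad strict fold-enrichment threshold for broad/island marks
#'   (default 1.5).
#' @slot mergeBookended if TRUE (default) abutting validated peaks are
#'   joined when merging.
#' @slot clipToOverlap if TRUE emit clipped overlap segments instead of
#'   whole validated peak records (default FALSE: whole-record retention).
#' @export
setClass("ValidationConfig",
    representation(feNarrow = "numeric", feBroad = "numeric",
                   mergeBookended = "logical", clipToOverlap = "logical"))

setValidity("ValidationConfig", function(object) {
    if (object@feNarrow <= 0 || object@feBroad <= 0)
        "fold-enrichment thresholds must be > 0"
    else TRUE
})

#' Construct a ValidationConfig
#'
#' @param feNarrow,feBroad strict FE thresholds for narrow (2.0) and
#'   broad/island (1.5) marks.
#' @param mergeBookended join abutting validated peaks when merging.
#' @param clipToOverlap emit clipped overlap segments instead of whole
#'   peak records.
#' @return a \linkS4class{ValidationConfig}.
#' @export
validationConfig <- function(feNarrow = 2.0, feBroad = 1.5,
                             mergeBookended = TRUE, clipToOverlap = FALSE) {
    new("ValidationConfig", feNarrow = feNarrow, feBroad = feBroad,
        mergeBookended = mergeBookended, clipToOverlap = clipToOverlap)
}
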