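## TSS-anchored feature annotation. Each peak gets exactly one category by
## the fixed priority Promoter > 5' UTR > 3' UTR > Exon > Intron >
## Downstream > Distal Intergenic, evaluated at the peak anchor (midpoint
## by default, summit when requested and present). Gene models here carry
## exons but no CDS records, so the UTR categories are structurally empty
## and their mass flows to Exon; the levels are kept in all outputs.

FEATURE_CATEGORIES <- c("Promoter", "5' UTR", "3' UTR", "Exon", "Intron",
    "Downstream", "Distal Intergenic")

#' Build a feature index from gene models
#'
#' Precomputes strand-aware promoter windows (TSS +/- promoterWindow) and
#' downstream windows (downstreamWindow bp past the transcript 3' end),
#' clipped to the chromosome when the models carry a genome.
#'
#' @param models a non-empty \linkS4class{GeneModels} object.
#' @param promoterWindow promoter half-width in bp (default 1000).
#' @param downstreamWindow downstream window in bp (default 300).
#' @return a \linkS4class{FeatureIndex}.
#' @export
buildFeatureIndex <- function(models, promoterWindow = 1000L,
                              downstreamWindow = 300L) {
    stopifnot(is(models, "GeneModels"))
    if (length(models@transcripts) == 0L)
        stop("cannot build a feature index from an empty gene-model list")
    promoterWindow <- as.integer(promoterWindow)
    downstreamWindow <- as.integer(downstreamWindow)
    if (promoterWindow < 1L || downstreamWindow < 1L)
        stop("annotation windows must be positive")
    tx <- models@transcripts
    tss <- transcriptTss(models)
    prom <- suppressWarnings(trim(promoters(tss, upstream = promoterWindow,
        downstream = promoterWindow)))
    down <- suppressWarnings(trim(flank(tx, width = downstreamWindow,
        start = FALSE)))
    new("FeatureIndex", models = models, promoters = prom,
        downstream = down, tss = tss,
        promoterWindow = promoterWindow,
        downstreamWindow = downstreamWindow)
}

.peakAnchors <- function(peaks, anchor = c("midpoint", "summit")) {
    anchor <- match.arg(anchor)
    pos <- floor((start(peaks) - 1 + end(peaks)) / 2) + 1L
    if (anchor == "summit") {
        so <- mcols(peaks)$summitOffset
        if (!is.null(so))
            pos <- ifelse(is.na(so), pos, start(peaks) + so)
    }
    GRanges(as.character(seqnames(peaks)), IRanges(pos, pos), strand = "*")
}

## For each query in `hits`, pick the candidate transcript minimizing
## (|anchor - TSS|, chrom, TSS, geneId, txId) - the deterministic
## tie-break order.
.pickTranscript <- function(hits, txIdx, anchorPos, anchorChr, index) {
    tss <- index@tss
    q <- queryHits(hits)
    s <- txIdx[subjectHits(hits)]
    d <- abs(anchorPos[q] - start(tss)[s])
    ord <- order(q, d, as.character(seqnames(tss))[s], start(tss)[s],
        mcols(tss)$geneId[s], mcols(tss)$txId[s])
    q <- q[ord]; s <- s[ord]
    keep <- !duplicated(q)
    list(query = q[keep], tx = s[keep])
}

#' Annotate peaks to genomic features
#'
#' Assigns each peak one category and one nearest transcript/gene with a
#' signed TSS distance (positive = downstream of the TSS in the gene's
#' orientation, negative = upstream; 0 at the TSS itself). The anchor is
#' the peak midpoint by default; with \code{anchor = "summit"} the summit
#' is used where present (midpoint fallback). Peaks on chromosomes
#' without any gene model get category "Distal Intergenic" and an NA
#' distance.
#'
#' @param peaks a \linkS4class{PeakSet}.
#' @param index a \linkS4class{FeatureIndex}.
#' @param anchor "midpoint" or "summit".
#' @return a \code{data.frame} with columns \code{peak}, \code{category}
#'   (factor over the seven feature levels), \code{geneId}, \code{txId},
#'   \code{tssDistance}.
#' @export
annotatePeaks <- function(peaks, index, anchor = c("midpoint", "summit")) {
    stopifnot(is(peaks, "GRanges"), is(index, "FeatureIndex"))
    anchor <- match.arg(anchor)
    n <- length(peaks)
    anchors <- .peakAnchors(peaks, anchor)
    anchorPos <- start(anchors)
    tx <- index@models@transcripts
    txIdsAll <- mcols(tx)$txId
    category <- rep("Distal Intergenic", n)
    chosenTx <- rep(NA_integer_, n)
    assigned <- rep(FALSE, n)

    assign_stage <- function(hits, txIdx, label) {
        sel <- .pickTranscript(hits, txIdx, anchorPos, NULL, index)
        fresh <- !assigned[sel$query]
        q <- sel$query[fresh]; s <- sel$tx[fresh]
        category[q] <<- label
        chosenTx[q] <<- s
        assigned[q] <<- TRUE
    }

    ov <- function(subject) suppressWarnings(
        findOverlaps(anchors, subject, ignore.strand = TRUE))

    if (n > 0L) {
        assign_stage(ov(index@promoters), seq_along(tx), "Promoter")
        exGr <- unlist(index@models@exons)
        exTx <- rep(seq_along(tx), lengths(index@models@exons))
        assign_stage(ov(exGr), exTx, "Exon")
        assign_stage(ov(tx), seq_along(tx), "Intron")
        assign_stage(ov(index@downstream), seq_along(tx), "Downstream")
        ## distal: nearest TSS genome-wide, deterministic tie-break
        todo <- which(!assigned)
        if (length(todo) > 0L) {
            dn <- suppressWarnings(distanceToNearest(anchors[todo],
                index@tss, select = "all", ignore.strand = TRUE))
            if (length(dn) > 0L) {
                h <- Hits(from = todo[queryHits(dn)], to = subjectHits(dn),
                    nLnode = n, nRnode = length(index@tss),
                    sort.by.query = TRUE)
                sel <- .pickTranscript(h, seq_along(tx), anchorPos, NULL,
                    index)
                chosenTx[sel$query] <- sel$tx
            }
        }
    }

    dist <- rep(NA_real_, n)
    ok <- !is.na(chosenTx)
    if (any(ok)) {
        tssPos <- start(index@tss)[chosenTx[ok]]
        minus <- as.character(strand(tx))[chosenTx[ok]] == "-"
        d <- anchorPos[ok] - tssPos
        d[minus] <- -d[minus]
        dist[ok] <- d
    }
    nm <- mcols(peaks)$name
    if (is.null(nm)) nm <- sprintf("peak_%d", seq_len(n))
    data.frame(
        peak = nm,
        category = factor(category, levels = FEATURE_CATEGORIES),
        geneId = ifelse(ok, mcols(tx)$geneId[chosenTx], NA_character_),
        txId = ifelse(ok, txIdsAll[chosenTx], NA_character_),
        tssDistance = dist,
        stringsAsFactors = FALSE)
}

#' Feature-category percentages of a peak set
#'
#' @param peaks a non-empty \linkS4class{PeakSet}.
#' @param index a \linkS4class{FeatureIndex}.
#' @param anchor passed to [annotatePeaks()].
#' @return named numeric over the seven feature categories, summing to
#'   100.
#' @export
annotationDistribution <- function(peaks, index,
                                   anchor = c("midpoint", "summit")) {
    if (length(peaks) == 0L)
        stop("annotation distribution is undefined for an empty peak set")
    ann <- annotatePeaks(peaks, index, match.arg(anchor))
    100 * table(ann$category) / nrow(ann)
}

#' TSS-distance distribution of a peak set
#'
#' Bins the unsigned anchor-to-nearest-TSS distances (default bins 0-1 kb,
#' 1-3 kb, 3-5 kb, 5-10 kb, 10-100 kb, >100 kb). Peaks without a TSS on
#' their chromosome are excluded; percentages are over the annotated
#' peaks and sum to 100.
#'
#' @param peaks a non-empty \linkS4class{PeakSet}.
#' @param index a \linkS4class{FeatureIndex}.
#' @param binEdges increasing distance bin edges starting at 0; the last
#'   may be \code{Inf}.
#' @param anchor passed to [annotatePeaks()].
#' @return named numeric of per-bin percentages.
#' @export
tssDistanceDistribution <- function(peaks, index,
        binEdges = c(0, 1e3, 3e3, 5e3, 1e4, 1e5, Inf),
        anchor = c("midpoint", "summit")) {
    if (length(peaks) == 0L)
        stop("TSS-distance distribution is undefined for an empty peak set")
    ann <- annotatePeaks(peaks, index, match.arg(anchor))
    d <- abs(ann$tssDistance)
    d <- d[!is.na(d)]
    if (length(d) == 0L)
        stop("no peak has a TSS on its chromosome")
    lab <- .binLabels(binEdges)
    b <- cut(d, breaks = binEdges, labels = lab, right = FALSE,
        include.lowest = TRUE)
    100 * table(b) / length(d)
}

.binLabels <- function(edges) {
    fmt <- function(x) {
        ifelse(x >= 1000, paste0(x / 1000, "kb"), paste0(x, "bp"))
    }
    n <- length(edges) - 1L
    lab <- character(n)
    for (i in seq_len(n)) {
        lab[i] <- if (is.infinite(edges[i + 1L]))
            paste0(">", fmt(edges[i])) else
            paste0(fmt(edges[i]), "-", fmt(edges[i + 1L]))
    }
    lab
}
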