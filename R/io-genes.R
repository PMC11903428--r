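## Gene-model input. GTF (Ensembl dialect, 1-based inclusive -> converted
## to the internal convention by rtracklayer) or BED12. The TSS of a
## + strand transcript is its span start; of a - strand transcript its
## span end.

#' Read transcript models from GTF or BED12
#'
#' For GTF, transcript spans are taken from \code{transcript} features
#' when present, otherwise inferred as the exon envelope per
#' \code{transcript_id}; \code{gene_id}/\code{transcript_id} attributes
#' are required (quoted or unquoted). For BED12 the block structure gives
#' the exons and the name column serves as both gene and transcript id.
#'
#' @param path file path.
#' @param dialect "gtf" or "bed12".
#' @param genome optional \code{Seqinfo} for validation.
#' @return a \linkS4class{GeneModels} object (one model per transcript).
#' @export
readGeneModels <- function(path, dialect = c("gtf", "bed12"),
                           genome = NULL) {
    dialect <- match.arg(dialect)
    models <- switch(dialect,
        gtf = .modelsFromGtf(path),
        bed12 = .modelsFromBed12(path))
    if (!is.null(genome)) {
        checkAgainstGenome(models@transcripts, genome)
        seqlevels(models@transcripts) <- seqlevels(genome)
        seqinfo(models@transcripts) <- genome
    }
    validObject(models)
    models
}

.modelsFromGtf <- function(path) {
    gr <- rtracklayer::import(path, format = "gtf")
    mc <- mcols(gr)
    if (!all(c("gene_id", "transcript_id") %in% names(mc)))
        stop("GTF must carry gene_id and transcript_id attributes")
    ex <- gr[mc$type == "exon"]
    if (length(ex) == 0L)
        stop("GTF contains no exon features")
    if (any(!as.character(strand(ex)) %in% c("+", "-")))
        stop(sprintf("missing strand for transcript '%s'",
            mcols(ex)$transcript_id[
                !as.character(strand(ex)) %in% c("+", "-")][1L]))
    exByTx <- split(granges(ex), mcols(ex)$transcript_id)
    exByTx <- GRangesList(lapply(exByTx, sort))
    txIds <- names(exByTx)
    txRows <- gr[mcols(gr)$type == "transcript"]
    if (length(txRows) > 0L && all(txIds %in% mcols(txRows)$transcript_id)) {
        txRows <- txRows[match(txIds, mcols(txRows)$transcript_id)]
        spans <- granges(txRows)
    } else {
        spans <- unlist(range(exByTx))[txIds]
    }
    geneIds <- mcols(ex)$gene_id[match(txIds, mcols(ex)$transcript_id)]
    mcols(spans) <- DataFrame(txId = txIds, geneId = geneIds)
    names(spans) <- NULL
    ord <- order(as.integer(seqnames(spans)), start(spans), end(spans))
    spans <- spans[ord]
    exByTx <- exByTx[ord]
    txIds <- txIds[ord]
    bad <- vapply(seq_along(spans), function(i) {
        e <- exByTx[[i]]
        any(start(e) < start(spans)[i]) || any(end(e) > end(spans)[i])
    }, logical(1L))
    if (any(bad))
        stop(sprintf("exon outside transcript span for '%s'",
            txIds[bad][1L]))
    GeneModels(spans, exByTx)
}

.modelsFromBed12 <- function(path) {
    gr <- rtracklayer::import(path, format = "bed")
    if (!"blocks" %in% names(mcols(gr)))
        stop("BED12 input must carry block structure (12 columns)")
    if (any(!as.character(strand(gr)) %in% c("+", "-")))
        stop("BED12 transcripts must be stranded")
    exons <- GRangesList(lapply(seq_along(gr), function(i) {
        rel <- mcols(gr)$blocks[[i]]
        GRanges(seqnames(gr)[i],
            shift(rel, start(gr)[i] - 1L), strand = strand(gr)[i])
    }))
    spans <- granges(gr)
    nm <- mcols(gr)$name
    if (is.null(nm)) nm <- sprintf("tx_%d", seq_along(gr))
    mcols(spans) <- DataFrame(txId = nm, geneId = nm)
    names(spans) <- NULL
    GeneModels(spans, exons)
}

#' Transcription start sites of gene models
#'
#' @param models a \linkS4class{GeneModels} object.
#' @return width-1 \code{GRanges} at each transcript's TSS (span start on
#'   +, span end on -), carrying \code{txId} and \code{geneId}.
#' @export
transcriptTss <- function(models) {
    tx <- models@transcripts
    pos <- ifelse(as.character(strand(tx)) == "+", start(tx), end(tx))
    out <- GRanges(seqnames(tx), IRanges(pos, pos), strand = strand(tx))
    mcols(out) <- mcols(tx)
    seqinfo(out) <- seqinfo(tx)
    out
}

#' Write gene models as GTF (Ensembl-style dialect)
#'
#' Emits one \code{transcript} row and its \code{exon} rows per model,
#' with quoted \code{gene_id}/\code{transcript_id} attributes.
#'
#' @param models a \linkS4class{GeneModels} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGeneModelsGtf <- function(models, path) {
    tx <- models@transcripts
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_along(tx)) {
        attr <- sprintf('gene_id "%s"; transcript_id "%s";',
            mcols(tx)$geneId[i], mcols(tx)$txId[i])
        writeLines(sprintf("%s\tChIPpanel\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
            as.character(seqnames(tx)[i]), start(tx)[i], end(tx)[i],
            as.character(strand(tx)[i]), attr), con)
        e <- models@exons[[i]]
        for (j in seq_along(e))
            writeLines(sprintf("%s\tChIPpanel\texon\t%d\t%d\t.\t%s\t.\t%s",
                as.character(seqnames(tx)[i]), start(e)[j], end(e)[j],
                as.character(strand(tx)[i]), attr), con)
    }
    invisible(path)
}
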