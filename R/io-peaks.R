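## Strict readers/writers for ENCODE narrowPeak (BED6+4) and broadPeak
## (BED6+3). Malformed rows are rejected with the offending line number,
## never silently repaired. File coordinates are 0-based half-open.

.parseNum <- function(v, what, lineno) {
    out <- suppressWarnings(as.numeric(v))
    bad <- is.na(out) & !is.na(v)
    if (any(bad))
        stop(sprintf("line %d: non-numeric %s field '%s'",
            lineno[bad][1L], what, v[bad][1L]))
    out
}

.readPeakLines <- function(path, ncol, what) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L)
        return(NULL)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != ncol))
        stop(sprintf("line %d: expected %d tab-separated %s columns, got %d",
            which(nf != ncol)[1L], ncol, what, nf[nf != ncol][1L]))
    mat <- matrix(unlist(fields), ncol = ncol, byrow = TRUE)
    lineno <- seq_len(nrow(mat))
    start <- .parseNum(mat[, 2L], "start", lineno)
    end <- .parseNum(mat[, 3L], "end", lineno)
    if (any(start != floor(start) | end != floor(end)))
        stop(sprintf("line %d: non-integer coordinate",
            which(start != floor(start) | end != floor(end))[1L]))
    if (any(start >= end))
        stop(sprintf("line %d: malformed interval (start >= end)",
            which(start >= end)[1L]))
    if (any(start < 0))
        stop(sprintf("line %d: negative start", which(start < 0)[1L]))
    list(mat = mat, start = start, end = end, lineno = lineno)
}

.peaksFromMat <- function(p, summit, genome) {
    mat <- p$mat
    fe <- .parseNum(mat[, 7L], "signalValue", p$lineno)
    lp <- .parseNum(mat[, 8L], "-log10 p", p$lineno)
    lq <- .parseNum(mat[, 9L], "-log10 q", p$lineno)
    if (any(fe < 0, na.rm = TRUE))
        stop(sprintf("line %d: negative fold enrichment",
            which(fe < 0)[1L]))
    gr <- GRanges(mat[, 1L], IRanges(p$start + 1L, p$end), strand = "*",
        name = mat[, 4L],
        score = .parseNum(mat[, 5L], "score", p$lineno),
        foldEnrichment = fe, neglog10P = lp, neglog10Q = lq)
    if (!is.null(summit)) {
        so <- as.integer(summit)
        so[so == -1L] <- NA_integer_
        bad <- !is.na(so) & (so < 0L | so >= width(gr))
        if (any(bad))
            stop(sprintf("line %d: summit offset outside peak",
                which(bad)[1L]))
        mcols(gr)$summitOffset <- so
    } else {
        mcols(gr)$summitOffset <- NA_integer_
    }
    if (!is.null(genome)) {
        checkAgainstGenome(gr, genome)
        seqlevels(gr) <- seqlevels(genome)
        seqinfo(gr) <- genome
    }
    gr
}

#' Read a narrowPeak / broadPeak file
#'
#' narrowPeak is BED6+4 (signalValue = fold enrichment over input,
#' -log10 p, -log10 q, summit offset; a summit of -1 maps to "absent");
#' broadPeak is BED6+3 without the summit column. Rows failing validation
#' raise an error naming the line.
#'
#' @param path file path.
#' @param genome optional \code{Seqinfo}; when given, peaks are validated
#'   against it.
#' @param mark,tissue,replicate labels attached to the returned set.
#' @return a \linkS4class{PeakSet} (callerStyle "narrow" or "broad"),
#'   sorted on load.
#' @export
readNarrowPeak <- function(path, genome = NULL, mark = "", tissue = "",
                           replicate = "") {
    p <- .readPeakLines(path, 10L, "narrowPeak")
    if (is.null(p))
        return(PeakSet(GRanges(), mark, tissue, replicate, "narrow"))
    summit <- .parseNum(p$mat[, 10L], "summit", p$lineno)
    gr <- .peaksFromMat(p, summit, genome)
    PeakSet(gr, mark, tissue, replicate, "narrow")
}

#' @rdname readNarrowPeak
#' @param callerStyle "broad" (default) or "island" for broadPeak input
#'   from an island-style caller.
#' @export
readBroadPeak <- function(path, genome = NULL, mark = "", tissue = "",
                          replicate = "",
                          callerStyle = c("broad", "island")) {
    callerStyle <- match.arg(callerStyle)
    p <- .readPeakLines(path, 9L, "broadPeak")
    if (is.null(p))
        return(PeakSet(GRanges(), mark, tissue, replicate, callerStyle))
    gr <- .peaksFromMat(p, NULL, genome)
    PeakSet(gr, mark, tissue, replicate, callerStyle)
}

.fmt <- function(x) {
    ifelse(is.na(x), ".", formatC(signif(x, 6L), format = "fg", flag = "#",
        digits = 6L))
}

#' Write peaks as narrowPeak / broadPeak / BED
#'
#' Writers are exact inverses of the readers (numeric scores at 6
#' significant digits); \code{writePeaksBed} emits plain BED6 with a zero
#' score, used for combined peak sets that carry no scores.
#'
#' @param x a \linkS4class{PeakSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeNarrowPeak <- function(x, path) {
    .writePeakFile(x, path, summit = TRUE)
}

#' @rdname writeNarrowPeak
#' @export
writeBroadPeak <- function(x, path) {
    .writePeakFile(x, path, summit = FALSE)
}

.writePeakFile <- function(x, path, summit) {
    stopifnot(is(x, "PeakSet"))
    mc <- mcols(x)
    nm <- if ("name" %in% names(mc)) mc$name else
        sprintf("peak_%d", seq_along(x))
    sc <- if ("score" %in% names(mc)) mc$score else rep(0, length(x))
    fe <- if ("foldEnrichment" %in% names(mc)) mc$foldEnrichment else
        rep(0, length(x))
    lp <- if ("neglog10P" %in% names(mc)) mc$neglog10P else rep(0, length(x))
    lq <- if ("neglog10Q" %in% names(mc)) mc$neglog10Q else rep(0, length(x))
    cols <- list(as.character(seqnames(x)), start(x) - 1L, end(x),
        nm, .fmt(sc), rep(".", length(x)), .fmt(fe), .fmt(lp), .fmt(lq))
    if (summit) {
        so <- if ("summitOffset" %in% names(mc)) mc$summitOffset else
            rep(NA_integer_, length(x))
        so[is.na(so)] <- -1L
        cols <- c(cols, list(so))
    }
    .writeTsv(cols, path)
    invisible(path)
}

#' @rdname writeNarrowPeak
#' @export
writePeaksBed <- function(x, path) {
    stopifnot(is(x, "GRanges"))
    mc <- mcols(x)
    nm <- if ("name" %in% names(mc)) mc$name else
        sprintf("peak_%d", seq_along(x))
    .writeTsv(list(as.character(seqnames(x)), start(x) - 1L, end(x),
        nm, rep(0L, length(x)), rep(".", length(x))), path)
    invisible(path)
}

.writeTsv <- function(cols, path) {
    df <- as.data.frame(cols, optional = TRUE, stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = FALSE)
    invisible(path)
}
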