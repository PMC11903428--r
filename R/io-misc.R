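## chrom.sizes, fragment BED and bedGraph input/output.

#' Read a two-column chrom.sizes file into a genome index
#'
#' @param path path to a tab-separated chromosome/length table.
#' @return a \code{Seqinfo}.
#' @export
readChromSizes <- function(path) {
    df <- read.table(path, sep = "\t", header = FALSE,
        col.names = c("chrom", "length"),
        colClasses = c("character", "numeric"))
    if (anyDuplicated(df$chrom))
        stop(sprintf("duplicate chromosome name '%s' in %s",
            df$chrom[duplicated(df$chrom)][1L], path))
    if (any(!nzchar(df$chrom)))
        stop("empty chromosome name")
    if (any(is.na(df$length) | df$length < 1))
        stop("chromosome lengths must be positive integers")
    Seqinfo(seqnames = df$chrom, seqlengths = as.integer(df$length))
}

#' Write a genome index as chrom.sizes
#'
#' @param genome a \code{Seqinfo}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeChromSizes <- function(genome, path) {
    sl <- seqlengths(genome)
    .writeTsv(list(names(sl), unname(sl)), path)
    invisible(path)
}

#' Read usable fragments from a BED file
#'
#' Accepts BED3 or wider; only the first three columns are used. Each row
#' is one usable fragment (a deduplicated, quality-filtered read-pair
#' proxy spanning the full template).
#'
#' @param path file path.
#' @param genome optional \code{Seqinfo} for validation.
#' @param sample sample label.
#' @return a \linkS4class{FragmentSet}.
#' @export
readFragmentsBed <- function(path, genome = NULL, sample = "") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L)
        return(FragmentSet(GRanges(), sample))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop(sprintf("line %d: BED needs >= 3 columns", which(nf < 3L)[1L]))
    chrom <- vapply(fields, `[[`, character(1L), 1L)
    start <- .parseNum(vapply(fields, `[[`, character(1L), 2L), "start",
        seq_along(fields))
    end <- .parseNum(vapply(fields, `[[`, character(1L), 3L), "end",
        seq_along(fields))
    if (any(start >= end))
        stop(sprintf("line %d: malformed interval (start >= end)",
            which(start >= end)[1L]))
    if (any(start < 0))
        stop(sprintf("line %d: negative start", which(start < 0)[1L]))
    gr <- GRanges(chrom, IRanges(start + 1L, end), strand = "*")
    if (!is.null(genome)) {
        checkAgainstGenome(gr, genome)
        seqlevels(gr) <- seqlevels(genome)
        seqinfo(gr) <- genome
    }
    FragmentSet(gr, sample)
}

#' Write fragments as BED3
#'
#' @param x a \linkS4class{FragmentSet} (or \code{GRanges}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFragmentsBed <- function(x, path) {
    stopifnot(is(x, "GRanges"))
    .writeTsv(list(as.character(seqnames(x)), start(x) - 1L, end(x)), path)
    invisible(path)
}

#' Write binned coverage as bedGraph
#'
#' Rows are sorted and non-overlapping; runs of bins with the same value
#' are collapsed; zero-signal runs are omitted (an all-zero track has an
#' empty body); values are written at 6 significant digits; the last bin
#' is clipped to the chromosome end.
#'
#' @param cov a \linkS4class{BinnedCoverage}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBedGraph <- function(cov, path) {
    stopifnot(is(cov, "BinnedCoverage"))
    sl <- seqlengths(cov@seqinfo)
    bs <- cov@binSize
    out <- lapply(names(cov@values), function(chr) {
        v <- signif(cov@values[[chr]], 6L)
        if (length(v) == 0L) return(NULL)
        r <- rle(v)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        keep <- r$values != 0
        if (!any(keep)) return(NULL)
        data.frame(chrom = chr,
            start = (starts[keep] - 1L) * bs,
            end = pmin(ends[keep] * bs, sl[[chr]]),
            value = r$values[keep], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    if (is.null(out)) {
        file.create(path)
        return(invisible(path))
    }
    .writeTsv(list(out$chrom, out$start, out$end,
        formatC(out$value, format = "fg", flag = "#", digits = 6L)), path)
    invisible(path)
}

#' Read a bedGraph written on a known bin grid
#'
#' Reconstructs the \linkS4class{BinnedCoverage} a [writeBedGraph()] call
#' serialized: every row must align to the bin grid (the final row of a
#' chromosome may be clipped to the chromosome end) and unmentioned bins
#' are zero.
#'
#' @param path file path.
#' @param genome a \code{Seqinfo}.
#' @param binSize the bin grid the file was written on.
#' @return a \linkS4class{BinnedCoverage}.
#' @export
readBedGraph <- function(path, genome, binSize) {
    binSize <- as.integer(binSize)
    sl <- seqlengths(genome)
    values <- lapply(sl, function(L) numeric(ceiling(L / binSize)))
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines)) {
        fields <- strsplit(lines, "\t", fixed = TRUE)
        nf <- lengths(fields)
        if (any(nf != 4L))
            stop(sprintf("line %d: bedGraph needs 4 columns",
                which(nf != 4L)[1L]))
        for (i in seq_along(fields)) {
            f <- fields[[i]]
            chr <- f[1L]
            if (!chr %in% names(values))
                stop(sprintf("line %d: unknown chromosome '%s'", i, chr))
            s <- as.numeric(f[2L]); e <- as.numeric(f[3L])
            v <- as.numeric(f[4L])
            if (is.na(s) || is.na(e) || is.na(v) || s >= e)
                stop(sprintf("line %d: malformed bedGraph row", i))
            if (s %% binSize != 0)
                stop(sprintf("line %d: row not aligned to %d bp grid",
                    i, binSize))
            b0 <- s %/% binSize + 1L
            b1 <- ceiling(e / binSize)
            values[[chr]][b0:b1] <- v
        }
    }
    new("BinnedCoverage", seqinfo = genome, binSize = binSize,
        values = values)
}
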