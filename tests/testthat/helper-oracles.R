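## Shared fixtures and independent brute-force oracles. Oracles work on
## explicit per-base boolean arrays or linear scans and share no code with
## the implementation.

library(GenomicRanges)

toyGenome <- function(lengths = c(c1 = 10000L)) {
    Seqinfo(seqnames = names(lengths), seqlengths = unname(lengths))
}

## random intervals on a single-chromosome toy genome
randomIntervals <- function(n, chromLen = 10000L, chrom = "c1",
                            maxWidth = 200L) {
    s <- sample.int(chromLen - maxWidth, n, replace = TRUE)
    w <- sample.int(maxWidth, n, replace = TRUE)
    GRanges(chrom, IRanges(s, s + w - 1L))
}

peakset <- function(starts, ends, fe = NULL, chrom = "c1", mark = "",
                    tissue = "", replicate = "", style = "narrow") {
    gr <- if (length(starts) == 0L) GRanges() else
        GRanges(chrom, IRanges(starts, ends))
    if (!is.null(fe)) mcols(gr)$foldEnrichment <- fe
    PeakSet(gr, mark, tissue, replicate, style)
}

## per-base boolean-array union of covered bases, per chromosome
unionLengthOracle <- function(gr, chromLens) {
    total <- 0
    for (chr in names(chromLens)) {
        g <- gr[as.character(seqnames(gr)) == chr]
        if (length(g) == 0L) next
        covered <- logical(chromLens[[chr]])
        for (i in seq_along(g))
            covered[start(g)[i]:end(g)[i]] <- TRUE
        total <- total + sum(covered)
    }
    total
}

## linear-scan any-overlap test for a single query
overlapsOracle <- function(q, targets) {
    any(as.character(seqnames(targets)) == as.character(seqnames(q)) &
        start(targets) <= end(q) & end(targets) >= start(q))
}

fripOracle <- function(fragments, peaks) {
    hit <- vapply(seq_along(fragments), function(i)
        overlapsOracle(fragments[i], peaks), logical(1L))
    mean(hit)
}

## brute-force SES: exhaustive scan over candidate split points of the
## sample-ascending ordering (stable ties), candidates restricted to
## positive cumulative mass in both tracks, last maximizer on ties
sesOracle <- function(x, y) {
    ord <- order(x)
    xs <- x[ord]; ys <- y[ord]
    best <- -Inf; bestK <- NA_integer_
    for (k in seq_along(xs)) {
        cs <- sum(xs[seq_len(k)])
        cc <- sum(ys[seq_len(k)])
        if (cs <= 0 || cc <= 0) next
        d <- cc / sum(ys) - cs / sum(xs)
        if (d >= best) { best <- d; bestK <- k }
    }
    sum(xs[seq_len(bestK)]) / sum(ys[seq_len(bestK)])
}

flatCov <- function(cov) unlist(coverageValues(cov), use.names = FALSE)

## minimal two-gene models: one per strand
twoGeneModels <- function(genome = toyGenome(c(c1 = 50000L))) {
    tx <- GRanges("c1", IRanges(c(10001, 30001), c(14000, 34000)),
        strand = c("+", "-"), txId = c("txPlus", "txMinus"),
        geneId = c("gPlus", "gMinus"), seqinfo = genome)
    exons <- GRangesList(
        GRanges("c1", IRanges(c(10001, 12001), c(10500, 14000)),
            strand = "+", seqinfo = genome),
        GRanges("c1", IRanges(c(30001, 33501), c(30500, 34000)),
            strand = "-", seqinfo = genome))
    GeneModels(tx, exons)
}

smallDesign <- function(seed = 11L, ...) {
    simulationDesign(seed = seed,
        chromLengths = c(chr1 = 300000L, chr2 = 300000L),
        tissues = c("adipose", "brain", "heart", "lamina", "liver",
                    "lung", "muscle", "testis"),
        assays = list(
            `H3K27ac` = list(mark = "H3K27ac", style = "narrow",
                nPeaks = 30L, meanWidth = 1000, feMeanlog = log(3),
                targetFrip = 0.46, noisePeaks = 3L)),
        fragmentsPerSample = 600L, nGenes = 20L, ...)
}
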