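test_that("promoter windows are strand-aware and clipped", {
    gm <- twoGeneModels()
    idx <- buildFeatureIndex(gm)
    prom <- idx@promoters
    ## + strand: window centred on span start
    expect_equal(c(start(prom)[1], end(prom)[1]), c(9001, 11000))
    ## - strand: anchored at span end
    expect_equal(c(start(prom)[2], end(prom)[2]), c(33001, 35000))

    ## clipping at the chromosome start
    g <- toyGenome(c(c1 = 50000L))
    tx <- GRanges("c1", IRanges(300, 5000), strand = "+",
        txId = "t", geneId = "g", seqinfo = g)
    gmEdge <- GeneModels(tx, GRangesList(GRanges("c1", IRanges(300, 5000),
        strand = "+", seqinfo = g)))
    idxEdge <- buildFeatureIndex(gmEdge)
    expect_equal(start(idxEdge@promoters), 1)
    expect_equal(end(idxEdge@promoters), 1299)

    expect_error(buildFeatureIndex(GeneModels(GRanges(),
        GRangesList())), "empty gene-model")
    expect_error(buildFeatureIndex(gm, promoterWindow = 0), "positive")
})

test_that("annotatePeaks assigns the priority category at the peak midpoint", {
    gm <- twoGeneModels()   # + gene 10001-14000 (TSS 10001), - gene 30001-34000 (TSS 34000)
    idx <- buildFeatureIndex(gm)

    cases <- list(
        ## midpoint 200 bp downstream of the + TSS -> Promoter, +200
        list(ps = peakset(10101, 10301), cat = "Promoter", d = 200),
        ## upstream of + TSS -> negative distance
        list(ps = peakset(9501, 9701), cat = "Promoter", d = -400),
        ## inside exon 2 of the + gene, outside the promoter window
        list(ps = peakset(13001, 13401), cat = "Exon", d = 3200),
        ## intron of the + gene
        list(ps = peakset(11401, 11501), cat = "Intron", d = 1450),
        ## just past the + gene 3' end -> Downstream
        list(ps = peakset(14101, 14301), cat = "Downstream", d = 4200),
        ## - strand promoter: midpoint 100 bp before span end -> +100
        list(ps = peakset(33801, 33999), cat = "Promoter", d = 100),
        ## far from both genes -> Distal Intergenic; nearest TSS is the
        ## minus gene's, and sitting right of a minus TSS is upstream
        list(ps = peakset(48001, 48201), cat = "Distal Intergenic",
            d = -(48101 - 34000)))
    for (cs in cases) {
        ann <- annotatePeaks(cs$ps, idx)
        expect_equal(as.character(ann$category), cs$cat)
        expect_equal(ann$tssDistance, cs$d)
    }

    ## determinism: same input, same assignment
    ps <- peakset(c(9501, 13001), c(9701, 13401))
    expect_identical(annotatePeaks(ps, idx), annotatePeaks(ps, idx))
})

test_that("promoter beats exon when a peak anchor sits in both", {
    g <- toyGenome(c(c1 = 50000L))
    ## gene X exon covers 10000-12000; gene Y TSS at 11500 (promoter
    ## 10500-12500): anchor 11400 lies in both -> Promoter of Y
    tx <- GRanges("c1", IRanges(c(8001, 11500), c(12000, 16000)),
        strand = "+", txId = c("tX", "tY"), geneId = c("gX", "gY"),
        seqinfo = g)
    gm <- GeneModels(tx, GRangesList(
        GRanges("c1", IRanges(10000, 12000), strand = "+", seqinfo = g),
        GRanges("c1", IRanges(11500, 16000), strand = "+", seqinfo = g)))
    idx <- buildFeatureIndex(gm)
    ann <- annotatePeaks(peakset(11301, 11499), idx)
    expect_equal(as.character(ann$category), "Promoter")
    expect_equal(ann$geneId, "gY")
    expect_equal(ann$tssDistance, 11400 - 11500)
})

test_that("summit anchoring is used when requested and present", {
    gm <- twoGeneModels()
    idx <- buildFeatureIndex(gm)
    gr <- GRanges("c1", IRanges(9001, 13001), summitOffset = 1100L)
    ps <- PeakSet(gr)   # midpoint 11001 (promoter edge...), summit 10101
    byMid <- annotatePeaks(ps, idx, anchor = "midpoint")
    bySummit <- annotatePeaks(ps, idx, anchor = "summit")
    expect_equal(bySummit$tssDistance, 100)
    expect_equal(as.character(bySummit$category), "Promoter")
    expect_false(isTRUE(all.equal(byMid$tssDistance,
        bySummit$tssDistance)))
})

test_that("distributions sum to 100 and recover planted category mixtures", {
    gm <- twoGeneModels()
    idx <- buildFeatureIndex(gm)
    ## plant 4 promoter, 3 exon, 2 intron, 1 distal
    prom <- lapply(c(-500, -100, 100, 500), function(o)
        GRanges("c1", IRanges(10001 + o - 50, 10001 + o + 50)))
    exon <- lapply(c(12100, 12600, 13100), function(s)
        GRanges("c1", IRanges(s, s + 100)))
    intr <- lapply(c(11150, 11500), function(s)
        GRanges("c1", IRanges(s, s + 100)))
    dist <- list(GRanges("c1", IRanges(45001, 45101)))
    ps <- PeakSet(do.call(c, c(prom, exon, intr, dist)))
    dd <- annotationDistribution(ps, idx)
    expect_equal(sum(dd), 100)
    expect_equal(as.numeric(dd[c("Promoter", "Exon", "Intron",
        "Distal Intergenic")]), c(40, 30, 20, 10))
    expect_equal(as.numeric(dd[c("5' UTR", "3' UTR", "Downstream")]),
        c(0, 0, 0))

    ## all peaks in one promoter -> 100% promoter, 100% in 0-1 kb
    inProm <- PeakSet(do.call(c, prom))
    expect_equal(as.numeric(
        annotationDistribution(inProm, idx)["Promoter"]), 100)
    tss <- tssDistanceDistribution(inProm, idx)
    expect_equal(sum(tss), 100)
    expect_equal(as.numeric(tss["0bp-1kb"]), 100)

    ## mixed distances land in the right unsigned bins
    far <- PeakSet(c(GRanges("c1", IRanges(10001, 10001)),  # 0
        GRanges("c1", IRanges(8001, 8001)),                 # 2 kb up
        GRanges("c1", IRanges(16001, 16001)),               # 6 kb down
        GRanges("c1", IRanges(48001, 48001))))              # 14 kb from -TSS
    tssFar <- tssDistanceDistribution(far, idx)
    expect_equal(as.numeric(tssFar[c("0bp-1kb", "1kb-3kb", "5kb-10kb",
        "10kb-100kb")]), c(25, 25, 25, 25))
})

test_that("shrinking the promoter window never increases the promoter fraction", {
    gm <- twoGeneModels()
    set.seed(420)
    ps <- PeakSet(reduce(randomIntervals(120, 49000L, maxWidth = 400L)))
    wide <- annotationDistribution(ps, buildFeatureIndex(gm, 2000L))
    narrow <- annotationDistribution(ps, buildFeatureIndex(gm, 500L))
    expect_lte(narrow[["Promoter"]], wide[["Promoter"]])
})
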