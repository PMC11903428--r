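test_that("fold-enrichment filtering is strictly greater-than", {
    ps <- peakset(c(100, 300, 500), c(200, 400, 600),
        fe = c(1.9, 2.0, 2.1))
    kept <- filterByFoldEnrichment(ps, 2.0)
    expect_length(kept, 1)
    expect_equal(mcols(kept)$foldEnrichment, 2.1)

    expect_length(filterByFoldEnrichment(peakset(integer(0), integer(0)),
        2.0), 0)
    expect_length(filterByFoldEnrichment(ps, 0), 3)
    noFe <- peakset(100, 200)
    expect_error(filterByFoldEnrichment(noFe, 2), "foldEnrichment")
})

test_that("one-direction validation keeps whole overlapping records", {
    filt <- peakset(100, 200, fe = 3, mark = "H3K27ac", tissue = "liver")
    other <- peakset(150, 300, fe = 1, mark = "H3K27ac", tissue = "liver")
    v <- validateAgainstReplicate(filt, other)
    expect_equal(start(v), 100)   # untouched coordinates
    expect_equal(end(v), 200)

    disjoint <- peakset(500, 600, fe = 1, mark = "H3K27ac",
        tissue = "liver")
    expect_length(validateAgainstReplicate(filt, disjoint), 0)
    wrong <- peakset(150, 300, fe = 1, mark = "H3K4me3", tissue = "liver")
    expect_error(validateAgainstReplicate(filt, wrong), "mark mismatch")
})

test_that("combineReplicates implements the FE truth table", {
    ## three co-occurring regions + one A-only region, narrow threshold 2.0:
    ##   r1: FE 2.5 / 1.2 -> retained via A's record only (B's FE fails,
    ##       so B's record does not extend the merged peak)
    ##   r2: FE 1.8 / 1.9 -> dropped (FE passes in neither)
    ##   r3: FE 2.2 / 2.4 -> retained, both records merged
    ##   r4: only in A, FE 5.0 -> dropped (no replicate support)
    a <- peakset(c(100, 1000, 2000, 3000), c(200, 1100, 2100, 3100),
        fe = c(2.5, 1.8, 2.2, 5.0), mark = "H3K27ac", tissue = "liver")
    b <- peakset(c(120, 1020, 2050), c(220, 1120, 2150),
        fe = c(1.2, 1.9, 2.4), mark = "H3K27ac", tissue = "liver")
    comb <- combineReplicates(a, b)
    expect_equal(replicateLabel(comb), "combined")
    expect_length(comb, 2)
    expect_equal(start(comb), c(100, 2000))
    expect_equal(end(comb), c(200, 2150))
    expect_equal(mcols(comb)$nRecordsA, c(1, 1))
    expect_equal(mcols(comb)$nRecordsB, c(0, 1))

    ## symmetry on covered bases
    swapped <- combineReplicates(b, a)
    expect_equal(granges(swapped), granges(comb), ignore_attr = TRUE)

    ## identical replicates, all FE passing -> merged input peaks
    self <- combineReplicates(a, a)
    pass <- filterByFoldEnrichment(a, 2)
    expect_equal(granges(self),
        mergeIntervals(pass), ignore_attr = TRUE)

    ## empty replicate -> warning + empty combined set
    empty <- peakset(integer(0), integer(0), fe = numeric(0),
        mark = "H3K27ac", tissue = "liver")
    expect_warning(res <- combineReplicates(a, empty), "empty replicate")
    expect_length(res, 0)
})

test_that("broad marks use the 1.5 threshold and clipping mode clips", {
    a <- peakset(100, 300, fe = 1.7, mark = "H3K27me3", tissue = "liver",
        style = "broad")
    b <- peakset(200, 400, fe = 1.2, mark = "H3K27me3", tissue = "liver",
        style = "broad")
    comb <- combineReplicates(a, b)
    expect_length(comb, 1)      # 1.7 > 1.5 passes for broad
    expect_equal(c(start(comb), end(comb)), c(100, 300))

    clip <- combineReplicates(a, b,
        validationConfig(clipToOverlap = TRUE))
    expect_equal(c(start(clip), end(clip)), c(200, 300))

    ## as a narrow pair the same FE values fail
    an <- peakset(100, 300, fe = 1.7, mark = "H3K27ac", tissue = "x")
    bn <- peakset(200, 400, fe = 1.2, mark = "H3K27ac", tissue = "x")
    expect_length(combineReplicates(an, bn), 0)
})

test_that("lowering the FE threshold never removes combined covered bases", {
    set.seed(406)
    d <- smallDesign(seed = 31L)
    tp <- simulateTruthPeaks(d, "H3K27ac")
    t1 <- d$tissues[1]
    sim <- simulateReplicates(tp$truth[[t1]], d, log(3),
        tp$noise[[t1]]$repA, tp$noise[[t1]]$repB, seed = 77L)
    hi <- combineReplicates(sim$repA, sim$repB,
        validationConfig(feNarrow = 2.5))
    lo <- combineReplicates(sim$repA, sim$repB,
        validationConfig(feNarrow = 1.5))
    ## every base covered at the high threshold is covered at the low one
    expect_equal(unionLength(intersect(granges(hi), granges(lo))),
        unionLength(hi))
    ## and the combined set never leaves the union of both replicates
    both <- c(granges(sim$repA), granges(sim$repB))
    expect_equal(unionLength(intersect(granges(lo), both)),
        unionLength(lo))
})

test_that("combined sets recover exactly the planted concordant FE-passing truth", {
    for (seed in c(3L, 17L, 29L)) {
        d <- smallDesign(seed = seed)
        tp <- simulateTruthPeaks(d, "H3K27ac")
        for (t in d$tissues[1:2]) {
            sim <- simulateReplicates(tp$truth[[t]], d, log(3),
                tp$noise[[t]]$repA, tp$noise[[t]]$repB, seed = seed + 100L)
            comb <- combineReplicates(sim$repA, sim$repB)
            ti <- sim$truthInfo
            ## a replicate's record joins the union only when that
            ## replicate's own FE passes
            qualA <- ti$truthId[ti$inA & ti$inB & ti$feA > 2]
            qualB <- ti$truthId[ti$inA & ti$inB & ti$feB > 2]
            expected <- reduce(c(
                granges(sim$repA)[mcols(sim$repA)$name %in% qualA],
                granges(sim$repB)[mcols(sim$repB)$name %in% qualB]))
            expect_equal(granges(comb), expected, ignore_attr = TRUE)
            expect_length(comb, length(union(qualA, qualB)))
            ## no replicate-specific truth or noise region survives
            lost <- ti$truthId[xor(ti$inA, ti$inB)]
            lostGr <- granges(tp$truth[[t]])[
                mcols(tp$truth[[t]])$truthId %in% lost]
            if (length(lostGr) > 0L)
                expect_false(any(overlapsPeaks(lostGr, comb)))
        }
    }
})
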