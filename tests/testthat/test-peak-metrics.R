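test_that("frip counts each fragment once and handles the edge cases", {
    peaks <- peakset(c(1000, 5000), c(2000, 6000))
    frags <- FragmentSet(GRanges("c1", IRanges(
        c(1500, 1900, 5500, 8000), width = 200)))
    expect_equal(frip(frags, peaks), 0.75)
    expect_equal(frip(frags, peakset(integer(0), integer(0))), 0)
    whole <- peakset(1, 10000)
    expect_equal(frip(frags, whole), 1)
    expect_error(frip(FragmentSet(GRanges()), peaks), "empty fragment")
})

test_that("frip agrees with the per-fragment linear-scan oracle on planted data", {
    g <- toyGenome(c(c1 = 100000L))
    set.seed(407)
    peaks <- PeakSet(reduce(randomIntervals(40, 100000L, maxWidth = 800L)))
    fs <- simulateFragments(peaks, 2000, 0.46, g, seed = 408L)
    measured <- frip(fs, peaks)
    expect_equal(measured, fripOracle(fs, peaks))
    expect_equal(measured, floor(2000 * 0.46) / 2000)
})

test_that("genome coverage percent uses union semantics", {
    g <- toyGenome(c(c1 = 10000L))
    one <- peakset(1001, 2000)
    expect_equal(genomeCoveragePct(one, g), 10)
    dup <- peakset(c(1001, 1001), c(2000, 2000))
    expect_equal(genomeCoveragePct(dup, g), 10)

    set.seed(409)
    r <- PeakSet(randomIntervals(120, 10000L))
    expect_equal(genomeCoveragePct(r, g),
        100 * unionLengthOracle(granges(r), c(c1 = 10000L)) / 10000)
})

test_that("effective genome fraction merges all input samples", {
    g <- toyGenome(c(c1 = 100000L))
    whole <- FragmentSet(GRanges("c1", IRanges(1, 100000)))
    expect_equal(effectiveGenomeFraction(list(whole), g), 1)
    empty <- FragmentSet(GRanges())
    expect_equal(effectiveGenomeFraction(list(empty), g), 0)

    set.seed(410)
    ins <- list(FragmentSet(randomIntervals(150, 100000L)),
                FragmentSet(randomIntervals(150, 100000L)))
    merged <- c(granges(ins[[1]]), granges(ins[[2]]))
    expect_equal(effectiveGenomeFraction(ins, g),
        unionLengthOracle(merged, c(c1 = 100000L)) / 100000)
})

test_that("width statistics are standard order statistics", {
    expect_equal(unname(widthStats(peakset(1, 100))),
        c(100, 100, 100, 100))
    two <- peakset(c(1, 200), c(100, 299))
    expect_equal(widthStats(two)[["median"]], 100)
    expect_error(widthStats(peakset(integer(0), integer(0))), "empty")

    set.seed(411)
    r <- peakset(seq(1, 9000, by = 30),
        seq(1, 9000, by = 30) + sample.int(25, 300, replace = TRUE))
    w <- sort(width(r))
    expect_equal(unname(widthStats(r)),
        c(mean(w), (w[150] + w[151]) / 2, w[1], w[300]))
})

test_that("overlap fraction and nesting profile distinguish partial overlap from containment", {
    broad <- peakset(c(1000, 20000), c(10000, 30000), style = "island")
    nested <- peakset(c(2000, 4000, 6000, 21000), c(2500, 4500, 6500, 21500))
    expect_equal(overlapFraction(nested, broad), 1)
    expect_equal(nestingProfile(nested, broad), c(3, 1))

    disjoint <- peakset(50000, 51000)
    expect_equal(overlapFraction(disjoint, broad), 0)
    expect_equal(nestingProfile(disjoint, broad), c(0, 0))
    expect_error(overlapFraction(peakset(integer(0), integer(0)), broad),
        "empty")

    ## straddling: overlaps but is not contained
    straddle <- peakset(9500, 10500)
    expect_equal(overlapFraction(straddle, broad), 1)
    expect_equal(nestingProfile(straddle, broad), c(0, 0))
})

test_that("planted narrow-in-island panels recover the nesting design", {
    g <- toyGenome(c(c1 = 800000L, c2 = 800000L))
    sim <- simulateBroadVsNarrow(g, nIslands = 10L,
        islandMeanWidth = 12000, nNarrow = 60L, narrowMeanWidth = 1200,
        nestedFraction = 0.85, seed = 412L)
    expect_equal(overlapFraction(sim$narrow, sim$island), 0.85)
    expect_equal(sum(nestingProfile(sim$narrow, sim$island)),
        round(0.85 * 60))
    ## extremes
    all0 <- simulateBroadVsNarrow(g, nIslands = 5L,
        islandMeanWidth = 8000, nNarrow = 20L, narrowMeanWidth = 1000,
        nestedFraction = 0, seed = 413L)
    expect_equal(overlapFraction(all0$narrow, all0$island), 0)
    all1 <- simulateBroadVsNarrow(g, nIslands = 5L,
        islandMeanWidth = 12000, nNarrow = 20L, narrowMeanWidth = 1000,
        nestedFraction = 1, seed = 414L)
    expect_equal(overlapFraction(all1$narrow, all1$island), 1)
})

test_that("markSummary bundles the per-sample quality row", {
    g <- toyGenome(c(c1 = 100000L))
    peaks <- PeakSet(GRanges("c1", IRanges(c(1001, 50001), width = 1000)),
        "H3K27ac", "liver", "combined")
    frags <- list(
        rep1 = simulateFragments(peaks, 500, 0.5, g, seed = 415L),
        rep2 = simulateFragments(peaks, 500, 0.3, g, seed = 416L))
    row <- markSummary(peaks, frags, g)
    expect_equal(row$nPeaks, 2L)
    expect_equal(row$coveragePct, 2)
    expect_equal(row$frip.rep1, 0.5)
    expect_equal(row$frip.rep2, 0.3)
})
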