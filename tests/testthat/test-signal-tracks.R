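test_that("binCoverage counts fragments per bin with the >= 1 bp rule", {
    g <- toyGenome(c(c1 = 1000L))
    one <- FragmentSet(GRanges("c1", IRanges(110, 160)))
    cov <- binCoverage(one, g, 100L)
    expect_equal(lengths(coverageValues(cov)), c(c1 = 10L))
    expect_equal(coverageValues(cov)$c1,
        c(0, 1, 0, 0, 0, 0, 0, 0, 0, 0))

    ## a fragment spanning two bins increments both
    span <- FragmentSet(GRanges("c1", IRanges(195, 210)))
    expect_equal(binCoverage(span, g, 100L)@values$c1[1:3], c(0, 1, 1))

    ## per-base oracle on a random toy genome: a fragment touches bin i
    ## iff it covers some base in [100(i-1)+1, 100i]
    set.seed(421)
    frags <- FragmentSet(randomIntervals(200, 950L, maxWidth = 60L))
    got <- binCoverage(frags, g, 100L)@values$c1
    want <- vapply(seq_len(10), function(i) {
        lo <- 100 * (i - 1) + 1; hi <- 100 * i
        sum(start(frags) <= hi & end(frags) >= lo)
    }, numeric(1))
    expect_equal(got, want)
})

test_that("SES factor is 1 on identical tracks and halves when control doubles", {
    g <- toyGenome(c(c1 = 5000L))
    set.seed(422)
    frags <- FragmentSet(randomIntervals(300, 4900L, maxWidth = 80L))
    cov <- binCoverage(frags, g, 50L)
    expect_equal(sesScaleFactor(cov, cov), 1)

    doubled <- subtractInput(cov, cov, factor = -1)   # 2x the counts
    expect_equal(sesScaleFactor(cov, doubled),
        sesScaleFactor(cov, cov) / 2)

    zero <- binCoverage(FragmentSet(GRanges()), g, 50L)
    expect_error(sesScaleFactor(cov, zero), "all-zero control")
    expect_error(sesScaleFactor(zero, cov), "all-zero sample")
})

test_that("SES matches the exhaustive-k oracle on random grids", {
    g <- toyGenome(c(c1 = 3000L))
    set.seed(423)
    for (i in 1:5) {
        s <- binCoverage(FragmentSet(randomIntervals(150, 2900L)), g, 50L)
        c <- binCoverage(FragmentSet(randomIntervals(120, 2900L)), g, 50L)
        expect_equal(sesScaleFactor(s, c), sesOracle(flatCov(s),
            flatCov(c)))
    }
    ## uniform control vs enriched, deeper sample: background dominates
    ## the split point and the factor stays at most 1
    ctrl <- binCoverage(FragmentSet(
        GRanges("c1", IRanges(seq(1, 2951, by = 50), width = 40))), g, 50L)
    enriched <- FragmentSet(c(
        GRanges("c1", IRanges(seq(1, 2951, by = 50), width = 40)),
        GRanges("c1", IRanges(rep(seq(1, 241, by = 60), 4), width = 40))))
    samp <- binCoverage(enriched, g, 50L)
    f <- sesScaleFactor(samp, ctrl)
    expect_equal(f, sesOracle(flatCov(samp), flatCov(ctrl)))
    expect_lte(f, 1)
})

test_that("subtraction keeps negatives and averaging is the unweighted mean", {
    g <- toyGenome(c(c1 = 500L))
    a <- binCoverage(FragmentSet(GRanges("c1", IRanges(c(10, 110),
        width = 30))), g, 100L)
    ## sample == factor x control -> all zeros
    z <- subtractInput(a, a, factor = 1)
    expect_true(all(flatCov(z) == 0))
    ## negative values retained
    b <- subtractInput(a, a, factor = 2)
    expect_equal(flatCov(b), -flatCov(a))
    ## linearity in both arguments on random grids
    set.seed(424)
    x <- binCoverage(FragmentSet(randomIntervals(50, 450L)), g, 100L)
    y <- binCoverage(FragmentSet(randomIntervals
        (50, 450L)), g, 100L)
    expect_equal(flatCov(subtractInput(x, y, 0.7)),
        flatCov(x) - 0.7 * flatCov(y))
    ## averaging identical tracks is the identity
    expect_equal(coverageValues(averageReplicates(x, x)),
        coverageValues(x))
    expect_equal(flatCov(averageReplicates(x, y)),
        (flatCov(x) + flatCov(y)) / 2)
    ## grid mismatch is a shape error
    y2 <- binCoverage(FragmentSet(GRanges()), g, 50L)
    expect_error(averageReplicates(x, y2), "grids do not match")
})

test_that("the subtracted track is centred near zero outside planted peaks", {
    g <- toyGenome(c(c1 = 200000L))
    peaks <- PeakSet(GRanges("c1", IRanges(seq(10001, 180001,
        by = 20000), width = 1000)))
    sampleFs <- simulateFragments(peaks, 4000, 0.30, g, seed = 425L)
    inputFs <- simulateFragments(GRanges(), 4000, 0, g, seed = 426L)
    samp <- binCoverage(sampleFs, g, 200L)
    ctrl <- binCoverage(inputFs, g, 200L)
    sub <- subtractInput(samp, ctrl)
    bins <- GRanges("c1", IRanges(seq(1, 199801, by = 200), width = 200))
    ## keep clear of fragment-length bleed at the peak flanks
    outside <- !overlapsPeaks(bins, granges(peaks) + 200L)
    resid <- flatCov(sub)[outside]
    ## centred at zero at the scale of single-bin noise: SES picks its
    ## split point from the low-sample tail, which leaves a small
    ## conditional bias, so the background mean is compared to the bin
    ## noise, not to the standard error of the mean
    expect_lt(abs(mean(resid)), 3 * sd(resid))
})

test_that("the full track chain is deterministic", {
    g <- toyGenome(c(c1 = 50000L))
    peaks <- PeakSet(GRanges("c1", IRanges(c(5001, 20001), width = 2000)))
    fa <- simulateFragments(peaks, 800, 0.5, g, seed = 427L)
    fb <- simulateFragments(peaks, 800, 0.4, g, seed = 428L)
    inp <- simulateFragments(GRanges(), 800, 0, g, seed = 429L)
    t1 <- combinedSignalTrack(fa, fb, inp, inp, g, 50L)
    t2 <- combinedSignalTrack(fa, fb, inp, inp, g, 50L)
    expect_identical(coverageValues(t1), coverageValues(t2))
    f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
    writeBedGraph(t1, f1); writeBedGraph(t2, f2)
    expect_identical(readLines(f1), readLines(f2))
})
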