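## Synthetic-data generator with planted ground truth. Truth regions for
## every assay are laid out in disjoint slots separated by gaps larger
## than the replicate coordinate jitter, so distinct truth regions can
## never come to overlap in any replicate: planted recoveries are exact,
## not probabilistic. Fully deterministic under a fixed seed.

.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        set.seed(seed)
        return(expr)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
}

#' Parameters of a synthetic multi-tissue ChIP-seq study
#'
#' Defaults emulate an eight-tissue, two-replicate histone panel at desk
#' scale (a 3 x 1 Mb toy genome; the metrics downstream are scale-free):
#' narrow-mark mean peak widths 1360/1219/1535 bp and a broad mark at
#' 1650 bp with an island-style variant at 18466 bp; fold enrichment
#' drawn log-normally so that mass straddles the 2.0/1.5 validation
#' thresholds; replicate concordance 0.8; a 16% per-tissue unique
#' fraction (84% of peaks shared by more than one tissue); per-mark FRiP
#' targets 0.46/0.32/0.65/0.30/0.47; 200 bp fragments.
#'
#' @param seed integer seed governing every random draw.
#' @param chromLengths named integer vector of chromosome lengths.
#' @param tissues tissue labels (>= 2).
#' @param assays named list of assay specs; each needs \code{mark},
#'   \code{style} ("narrow"/"broad"/"island"), \code{nPeaks} (truth peaks
#'   per tissue), \code{meanWidth}, \code{feMeanlog}, \code{targetFrip},
#'   \code{noisePeaks} (replicate-specific noise peaks per tissue and
#'   replicate).
#' @param concordance probability a truth peak appears in both
#'   replicates (otherwise exactly one).
#' @param uniqueFraction fraction of each tissue's truth peaks planted as
#'   tissue-unique.
#' @param jitterFrac replicate coordinate jitter as a fraction of peak
#'   width (each edge moves by up to this fraction).
#' @param widthSdlog log-sd of the log-normal peak width distribution.
#' @param feSdlog log-sd of the log-normal fold-enrichment distribution.
#' @param fragmentsPerSample baseline usable fragments per sample.
#' @param fragLen fragment (template) length in bp.
#' @param nGenes synthetic transcript models for the annotation stage.
#' @return a \code{SimulationDesign} (a validated named list).
#' @export
simulationDesign <- function(
        seed = 1L,
        chromLengths = c(chr1 = 1000000L, chr2 = 1000000L,
                         chr3 = 1000000L),
        tissues = c("adipose", "brain", "heart", "lamina", "liver",
                    "lung", "muscle", "testis"),
        assays = list(
            `H3K27ac` = list(mark = "H3K27ac", style = "narrow",
                nPeaks = 120L, meanWidth = 1360, feMeanlog = log(3),
                targetFrip = 0.46, noisePeaks = 10L),
            `H3K4me1` = list(mark = "H3K4me1", style = "narrow",
                nPeaks = 150L, meanWidth = 1219, feMeanlog = log(3),
                targetFrip = 0.32, noisePeaks = 10L),
            `H3K4me3` = list(mark = "H3K4me3", style = "narrow",
                nPeaks = 90L, meanWidth = 1535, feMeanlog = log(3),
                targetFrip = 0.65, noisePeaks = 10L),
            `H3K27me3-M` = list(mark = "H3K27me3", style = "broad",
                nPeaks = 120L, meanWidth = 1650, feMeanlog = log(2.2),
                targetFrip = 0.30, noisePeaks = 10L),
            `H3K27me3-S` = list(mark = "H3K27me3", style = "island",
                nPeaks = 18L, meanWidth = 18466, feMeanlog = log(2.2),
                targetFrip = 0.47, noisePeaks = 2L)),
        concordance = 0.8,
        uniqueFraction = 0.16,
        jitterFrac = 0.1,
        widthSdlog = 0.3,
        feSdlog = 0.6,
        fragmentsPerSample = 4000L,
        fragLen = 200L,
        nGenes = 60L) {
    stopifnot(length(tissues) >= 2L, concordance >= 0, concordance <= 1,
        uniqueFraction >= 0, uniqueFraction <= 1, jitterFrac >= 0,
        jitterFrac < 0.5, fragLen >= 1L, fragmentsPerSample >= 0L,
        all(chromLengths > 0))
    for (a in assays)
        stopifnot(a$style %in% CALLER_STYLES, a$nPeaks >= 0,
            a$meanWidth >= 1, a$targetFrip >= 0, a$targetFrip <= 1)
    design <- list(seed = as.integer(seed), chromLengths = chromLengths,
        tissues = tissues, assays = assays, concordance = concordance,
        uniqueFraction = uniqueFraction, jitterFrac = jitterFrac,
        widthSdlog = widthSdlog, feSdlog = feSdlog,
        fragmentsPerSample = as.integer(fragmentsPerSample),
        fragLen = as.integer(fragLen), nGenes = as.integer(nGenes))
    class(design) <- "SimulationDesign"
    design
}

#' @export
print.SimulationDesign <- function(x, ...) {
    cat(sprintf(
        "SimulationDesign: %d tissues x %d assays on %d chromosomes (%d bp), seed %d\n",
        length(x$tissues), length(x$assays), length(x$chromLengths),
        sum(x$chromLengths), x$seed))
    invisible(x)
}

.designGenome <- function(design) {
    Seqinfo(seqnames = names(design$chromLengths),
        seqlengths = as.integer(design$chromLengths))
}

## Lay out regions of the given widths in genome order with jitter-proof
## gaps; the i-th returned region has widths[i].
.allocateRegions <- function(widths, chromLengths, margin = 500L) {
    n <- length(widths)
    if (n == 0L)
        return(GRanges())
    chroms <- names(chromLengths)
    chrom <- character(n)
    starts <- integer(n)
    ci <- 1L
    pos <- margin
    prevW <- 0L
    for (i in seq_len(n)) {
        w <- widths[i]
        repeat {
            if (ci > length(chroms))
                stop("genome too small for requested peak mass")
            gap <- as.integer(ceiling(0.12 * (w + prevW))) + 100L
            s <- pos + gap
            if (s + w - 1L <= chromLengths[[ci]] - margin)
                break
            ci <- ci + 1L
            pos <- margin
            prevW <- 0L
        }
        chrom[i] <- chroms[ci]
        starts[i] <- s
        pos <- s + w - 1L
        prevW <- w
    }
    GRanges(chrom, IRanges(starts, starts + widths - 1L))
}

.drawWidths <- function(n, meanWidth, sdlog) {
    pmax(1L, as.integer(round(rlnorm(n, log(meanWidth) - sdlog^2 / 2,
        sdlog))))
}

#' Plant per-tissue truth peaks for one assay
#'
#' Tissue-shared peaks come from a common pool present in every tissue;
#' tissue-unique peaks and per-replicate noise regions occupy their own
#' disjoint slots (separated from everything by more than the jitter
#' extent).
#'
#' @param design a \code{SimulationDesign}.
#' @param assay assay name in \code{design$assays}.
#' @param seed optional seed (defaults to the design seed).
#' @return list with \code{truth} (named list tissue ->
#'   \linkS4class{PeakSet} with \code{truthId} and \code{unique}
#'   metadata), \code{noise} (list tissue -> list(repA, repB) noise
#'   \code{GRanges}), and \code{regions} (the full region registry
#'   data.frame).
#' @export
simulateTruthPeaks <- function(design, assay, seed = design$seed) {
    spec <- design$assays[[assay]]
    if (is.null(spec)) stop(sprintf("unknown assay '%s'", assay))
    .withSeed(seed, .simulateTruthPeaks(design, assay, spec))
}

.simulateTruthPeaks <- function(design, assay, spec) {
    tissues <- design$tissues
    nT <- length(tissues)
    nUnique <- as.integer(round(design$uniqueFraction * spec$nPeaks))
    nShared <- spec$nPeaks - nUnique
    nNoise <- spec$noisePeaks
    roles <- c(rep("shared", nShared),
        rep(paste0("unique:", tissues), each = nUnique),
        rep(paste0("noiseA:", tissues), each = nNoise),
        rep(paste0("noiseB:", tissues), each = nNoise))
    n <- length(roles)
    widths <- .drawWidths(n, spec$meanWidth, design$widthSdlog)
    ord <- sample.int(n)
    ## chromosome-end margin must exceed the replicate jitter so jittered
    ## records always stay on the chromosome
    margin <- max(500L,
        as.integer(ceiling(design$jitterFrac * max(widths, 1L))) + 100L)
    alloc <- .allocateRegions(widths[ord], design$chromLengths, margin)
    regionsGr <- alloc[order(ord)]
    genome <- .designGenome(design)
    seqlevels(regionsGr) <- seqlevels(genome)
    seqinfo(regionsGr) <- genome
    ids <- sprintf("%s_r%04d", gsub("[^A-Za-z0-9]", "", assay), seq_len(n))
    registry <- data.frame(truthId = ids, role = roles,
        chrom = as.character(seqnames(regionsGr)),
        start0 = start(regionsGr) - 1L, end0 = end(regionsGr),
        stringsAsFactors = FALSE)
    truth <- list()
    noise <- list()
    for (t in tissues) {
        keep <- roles == "shared" | roles == paste0("unique:", t)
        gr <- regionsGr[keep]
        mcols(gr)$truthId <- ids[keep]
        mcols(gr)$unique <- roles[keep] != "shared"
        truth[[t]] <- PeakSet(gr, spec$mark, t, "truth", spec$style)
        noise[[t]] <- list(
            repA = regionsGr[roles == paste0("noiseA:", t)],
            repB = regionsGr[roles == paste0("noiseB:", t)])
        mcols(noise[[t]]$repA)$truthId <- ids[roles == paste0("noiseA:", t)]
        mcols(noise[[t]]$repB)$truthId <- ids[roles == paste0("noiseB:", t)]
    }
    list(truth = truth, noise = noise, regions = registry)
}

.jitter <- function(gr, frac) {
    if (length(gr) == 0L || frac == 0) return(gr)
    w <- width(gr)
    ds <- as.integer(round(runif(length(gr), -frac * w, frac * w)))
    de <- as.integer(round(runif(length(gr), -frac * w, frac * w)))
    GRanges(seqnames(gr), IRanges(start(gr) + ds, end(gr) + de),
        seqinfo = seqinfo(gr))
}

.peakScores <- function(gr, feMeanlog, feSdlog, style) {
    n <- length(gr)
    fe <- rlnorm(n, feMeanlog, feSdlog)
    lq <- runif(n, 5, 50)
    lp <- lq + runif(n, 1, 10)
    mcols(gr)$name <- mcols(gr)$truthId
    mcols(gr)$score <- round(10 * lq)
    mcols(gr)$foldEnrichment <- fe
    mcols(gr)$neglog10P <- lp
    mcols(gr)$neglog10Q <- lq
    mcols(gr)$summitOffset <- if (style == "narrow")
        as.integer((width(gr) - 1L) %/% 2L) else NA_integer_
    mcols(gr)$truthId <- NULL
    gr
}

#' Simulate two replicates from planted truth peaks
#'
#' Each truth peak appears in both replicates with probability
#' \code{concordance} and in exactly one otherwise; per-replicate
#' records get independent coordinate jitter and fold-enrichment draws;
#' replicate-specific noise peaks are appended.
#'
#' @param truth a truth \linkS4class{PeakSet} (metadata column
#'   \code{truthId}).
#' @param design a \code{SimulationDesign} (supplies concordance, jitter
#'   and FE distribution parameters).
#' @param feMeanlog log-mean of the FE distribution.
#' @param noiseA,noiseB replicate-specific noise regions
#'   (\code{GRanges} with \code{truthId}).
#' @param seed optional seed.
#' @return list with \code{repA}, \code{repB}
#'   (\linkS4class{PeakSet}s) and \code{truthInfo} (data.frame: truthId,
#'   inA, inB, feA, feB; NA FE when absent from a replicate).
#' @export
simulateReplicates <- function(truth, design, feMeanlog,
                               noiseA = GRanges(), noiseB = GRanges(),
                               seed = NULL) {
    stopifnot(is(truth, "PeakSet"))
    .withSeed(seed, {
        n <- length(truth)
        inBoth <- runif(n) < design$concordance
        aOnly <- !inBoth & runif(n) < 0.5
        inA <- inBoth | aOnly
        inB <- inBoth | (!inBoth & !aOnly)
        buildRep <- function(present, noise, lab) {
            rec <- .jitter(granges(truth)[present], design$jitterFrac)
            mcols(rec)$truthId <- mcols(truth)$truthId[present]
            if (length(noise) > 0L) {
                ngr <- .jitter(granges(noise), design$jitterFrac)
                mcols(ngr)$truthId <- mcols(noise)$truthId
                rec <- c(rec, ngr)
            }
            rec <- .peakScores(rec, feMeanlog, design$feSdlog,
                truth@callerStyle)
            PeakSet(rec, truth@mark, truth@tissue, lab, truth@callerStyle)
        }
        repA <- buildRep(inA, noiseA, "rep1")
        repB <- buildRep(inB, noiseB, "rep2")
        feOf <- function(rep, id) {
            m <- match(id, mcols(rep)$name)
            mcols(rep)$foldEnrichment[m]
        }
        ids <- mcols(truth)$truthId
        list(repA = repA, repB = repB,
            truthInfo = data.frame(truthId = ids, inA = inA, inB = inB,
                feA = feOf(repA, ids), feB = feOf(repB, ids),
                stringsAsFactors = FALSE))
    })
}

#' Simulate usable fragments with a planted in-peak fraction
#'
#' Places \code{floor(n * targetFrip)} fragments overlapping (>= 1 bp)
#' the peak set and the remainder in peak-free space, so the realized
#' FRiP equals the target up to the flooring.
#'
#' @param peaks a \linkS4class{PeakSet} or \code{GRanges} (may be empty
#'   when \code{targetFrip} is 0).
#' @param n number of fragments.
#' @param targetFrip planted in-peak fraction in [0, 1].
#' @param genome a \code{Seqinfo}.
#' @param fragLen fragment length in bp.
#' @param sample sample label.
#' @param seed optional seed.
#' @return a \linkS4class{FragmentSet}.
#' @export
simulateFragments <- function(peaks, n, targetFrip, genome,
                              fragLen = 200L, sample = "", seed = NULL) {
    stopifnot(targetFrip >= 0, targetFrip <= 1, n >= 0)
    .withSeed(seed, {
        merged <- if (length(peaks) > 0L) mergeIntervals(peaks) else
            GRanges()
        nIn <- as.integer(floor(n * targetFrip))
        nOut <- n - nIn
        if (nIn > 0L && length(merged) == 0L)
            stop("cannot place in-peak fragments without peaks")
        sl <- seqlengths(genome)
        frs <- list()
        if (nIn > 0L) {
            idx <- sample.int(length(merged), nIn, replace = TRUE,
                prob = width(merged))
            lo <- pmax(start(merged)[idx] - fragLen + 1L, 1L)
            hi <- pmin(end(merged)[idx],
                sl[as.character(seqnames(merged))[idx]] - fragLen + 1L)
            s <- pmin(as.integer(floor(runif(nIn, lo, hi + 1))), hi)
            gr <- GRanges(seqnames(merged)[idx],
                IRanges(s, s + fragLen - 1L))
            bad <- !overlapsPeaks(gr, merged)
            if (any(bad))  # clipped at a chromosome edge: recentre
                gr[bad] <- GRanges(seqnames(merged)[idx][bad], IRanges(
                    start(merged)[idx][bad],
                    start(merged)[idx][bad] + fragLen - 1L))
            frs <- c(frs, list(gr))
        }
        if (nOut > 0L) {
            placed <- GRanges()
            tries <- 0L
            cum <- cumsum(as.numeric(sl - fragLen + 1L))
            while (length(placed) < nOut) {
                if (tries >= 200L)
                    stop("cannot place fragments outside peaks ",
                         "(peaks cover the accessible genome)")
                need <- (nOut - length(placed)) * 2L + 10L
                u <- runif(need, 0, cum[length(cum)])
                ci <- findInterval(u, c(0, cum), rightmost.closed = TRUE)
                off <- u - c(0, cum)[ci]
                s <- as.integer(floor(off)) + 1L
                gr <- GRanges(names(sl)[ci], IRanges(s, s + fragLen - 1L))
                ok <- !overlapsPeaks(gr, merged)
                placed <- c(placed, gr[ok])
                tries <- tries + 1L
            }
            frs <- c(frs, list(placed[seq_len(nOut)]))
        }
        all <- if (length(frs)) do.call(c, frs) else GRanges()
        seqlevels(all) <- seqlevels(genome)
        seqinfo(all) <- genome
        FragmentSet(all, sample)
    })
}

#' Simulate a narrow caller / island caller pair with planted nesting
#'
#' Generates broad islands and narrow peaks of which a planted fraction
#' is fully nested inside islands (consecutive, non-overlapping) while
#' the rest lies entirely outside any island, so the narrow-in-island
#' overlap fraction equals the planted value exactly. Default widths and
#' counts keep island coverage at roughly 2.3x the narrow coverage.
#'
#' @param genome a \code{Seqinfo}.
#' @param nIslands,islandMeanWidth island count and mean width (bp).
#' @param nNarrow,narrowMeanWidth narrow-peak count and mean width (bp).
#' @param nestedFraction fraction of narrow peaks nested in islands.
#' @param widthSdlog log-sd of both width distributions.
#' @param seed optional seed.
#' @return list with \code{narrow} and \code{island}
#'   \linkS4class{PeakSet}s and logical \code{nested} along
#'   \code{narrow}.
#' @export
simulateBroadVsNarrow <- function(genome, nIslands = 25L,
        islandMeanWidth = 18466, nNarrow = 120L, narrowMeanWidth = 1650,
        nestedFraction = 0.85, widthSdlog = 0.2, seed = NULL) {
    stopifnot(nestedFraction >= 0, nestedFraction <= 1)
    .withSeed(seed, {
        sl <- seqlengths(genome)
        iw <- .drawWidths(nIslands, islandMeanWidth, widthSdlog)
        islands <- .allocateRegions(iw, as.list(sl))
        seqlevels(islands) <- seqlevels(genome)
        seqinfo(islands) <- genome
        nNested <- as.integer(round(nestedFraction * nNarrow))
        nw <- .drawWidths(nNarrow, narrowMeanWidth, widthSdlog)
        nested <- rep(c(TRUE, FALSE), c(nNested, nNarrow - nNested))
        narrowGr <- GRanges(seqinfo = genome)
        if (nNested > 0L) {
            ## capacity-aware greedy: each nested narrow goes to the
            ## island with the most remaining interior space
            remaining <- width(islands) - 100L
            host <- integer(nNested)
            for (j in seq_len(nNested)) {
                i <- which.max(remaining)
                if (remaining[i] < nw[j] + 100L)
                    stop("islands too small for the nested narrow peaks")
                host[j] <- i
                remaining[i] <- remaining[i] - nw[j] - 100L
            }
            inner <- GRanges(seqinfo = genome)
            for (i in seq_len(nIslands)) {
                ws <- nw[seq_len(nNested)][host == i]
                if (length(ws) == 0L) next
                pos <- start(islands)[i] + 50L
                ss <- integer(length(ws))
                for (j in seq_along(ws)) {
                    ss[j] <- pos
                    pos <- pos + ws[j] + 100L
                }
                inner <- c(inner, GRanges(seqnames(islands)[i],
                    IRanges(ss, ss + ws - 1L), seqinfo = genome))
            }
            narrowGr <- inner
        }
        nFree <- nNarrow - nNested
        if (nFree > 0L) {
            free <- GRanges(seqinfo = genome)
            freeW <- nw[nNested + seq_len(nFree)]
            cum <- cumsum(as.numeric(sl))
            tries <- 0L
            while (length(free) < nFree) {
                if (tries >= 500L)
                    stop("no island-free space for narrow peaks")
                i <- length(free) + 1L
                w <- freeW[i]
                u <- runif(1, 0, cum[length(cum)])
                ci <- findInterval(u, c(0, cum), rightmost.closed = TRUE)
                s <- as.integer(floor(u - c(0, cum)[ci])) + 1L
                if (s + w - 1L <= sl[[ci]]) {
                    cand <- GRanges(names(sl)[ci],
                        IRanges(s, s + w - 1L), seqinfo = genome)
                    if (!overlapsPeaks(cand, islands) &&
                        (length(narrowGr) == 0L ||
                         !overlapsPeaks(cand, narrowGr)) &&
                        (length(free) == 0L || !overlapsPeaks(cand, free)))
                        free <- c(free, cand)
                }
                tries <- tries + 1L
            }
            narrowGr <- c(narrowGr, free)
        }
        seqlevels(narrowGr) <- seqlevels(genome)
        seqinfo(narrowGr) <- genome
        o <- order(as.integer(seqnames(narrowGr)), start(narrowGr))
        list(
            narrow = PeakSet(narrowGr[o], "H3K27me3", "", "",
                "narrow"),
            island = PeakSet(islands, "H3K27me3", "", "", "island"),
            nested = nested[o])
    })
}

#' Simulate synthetic transcript models
#'
#' Gene spans laid out with the slot allocator, alternating strands,
#' 2-5 exons each; gene and transcript ids coincide.
#'
#' @param genome a \code{Seqinfo}.
#' @param nGenes number of transcripts.
#' @param meanLength mean gene length (bp).
#' @param seed optional seed.
#' @return a \linkS4class{GeneModels} object.
#' @export
simulateGeneModels <- function(genome, nGenes = 60L, meanLength = 8000,
                               seed = NULL) {
    .withSeed(seed, {
        sl <- seqlengths(genome)
        gw <- .drawWidths(nGenes, meanLength, 0.4)
        gw <- pmax(gw, 400L)
        spans <- .allocateRegions(gw, as.list(sl))
        strand(spans) <- rep(c("+", "-"), length.out = nGenes)
        seqlevels(spans) <- seqlevels(genome)
        seqinfo(spans) <- genome
        ids <- sprintf("TX%04d", seq_len(nGenes))
        mcols(spans) <- DataFrame(txId = ids,
            geneId = sprintf("G%04d", seq_len(nGenes)))
        exons <- GRangesList(lapply(seq_len(nGenes), function(i) {
            L <- width(spans)[i]
            k <- sample(2:5, 1L)
            cuts <- sort(sample.int(L - 2L, 2L * k - 2L)) + start(spans)[i]
            bounds <- c(start(spans)[i], cuts, end(spans)[i])
            s <- bounds[seq(1L, by = 2L, length.out = k)]
            e <- bounds[seq(2L, by = 2L, length.out = k)]
            e[k] <- end(spans)[i]
            keep <- s <= e
            GRanges(seqnames(spans)[i], IRanges(s[keep], e[keep]),
                strand = strand(spans)[i], seqinfo = seqinfo(spans))
        }))
        GeneModels(spans, exons)
    })
}
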