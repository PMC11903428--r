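## End-to-end orchestration over a fixture-bundle file tree, and
## recomputation of the vendored reference summary tables.

#' Run the full analysis over a fixture bundle
#'
#' Reads the bundle's manifest and executes every downstream stage:
#' replicate validation into combined peak BEDs, the per-sample summary
#' metrics table (peak counts, widths, genome coverage, FRiP per
#' replicate), per-assay tissue-uniqueness tables with the read-depth
#' correlation diagnostics, feature annotation with category and
#' TSS-distance distributions, and SES-scaled input-subtracted
#' replicate-averaged bedGraph tracks. Outputs are deterministic:
#' identical inputs give byte-identical report files.
#'
#' @param bundleDir directory written by [writeFixtureBundle()] (or laid
#'   out the same way).
#' @param outDir output directory (created).
#' @param config a \linkS4class{ValidationConfig}.
#' @param promoterWindow,downstreamWindow annotation windows in bp.
#' @param binSize track bin size in bp.
#' @param annotateStyles caller styles whose combined peaks are
#'   annotated (island-style peaks, being tens of kb wide, are excluded
#'   by default).
#' @param writeTracks set FALSE to skip bedGraph track generation.
#' @return invisibly, a list with the in-memory results (combined sets,
#'   metrics, uniqueness reports, annotation distributions).
#' @export
runPipeline <- function(bundleDir, outDir, config = validationConfig(),
                        promoterWindow = 1000L, downstreamWindow = 300L,
                        binSize = 50L,
                        annotateStyles = c("narrow", "broad"),
                        writeTracks = TRUE) {
    manifestPath <- file.path(bundleDir, "manifest.tsv")
    if (!file.exists(manifestPath))
        stop("stage ingest: no manifest.tsv in ", bundleDir)
    manifest <- read.table(manifestPath, sep = "\t", header = TRUE,
        stringsAsFactors = FALSE)
    genome <- readChromSizes(file.path(bundleDir, "genome", "chrom.sizes"))
    genes <- readGeneModels(file.path(bundleDir, "genes", "genes.gtf"),
        "gtf", genome)
    for (d in c("", "combined", "annotation", "tracks"))
        dir.create(file.path(outDir, d), showWarnings = FALSE,
            recursive = TRUE)
    index <- buildFeatureIndex(genes, promoterWindow, downstreamWindow)

    combined <- list()
    metricRows <- list()
    fragCache <- new.env(parent = emptyenv())
    readFrags <- function(rel, sample) {
        if (is.null(fragCache[[rel]]))
            fragCache[[rel]] <- readFragmentsBed(
                file.path(bundleDir, rel), genome, sample)
        fragCache[[rel]]
    }
    readPeaks <- function(rel, style, mark, tissue, rep) {
        path <- file.path(bundleDir, rel)
        if (style == "narrow")
            readNarrowPeak(path, genome, mark, tissue, rep)
        else readBroadPeak(path, genome, mark, tissue, rep,
            callerStyle = style)
    }
    for (i in seq_len(nrow(manifest))) {
        m <- manifest[i, ]
        repA <- readPeaks(m$rep1Peaks, m$style, m$mark, m$tissue, "rep1")
        repB <- readPeaks(m$rep2Peaks, m$style, m$mark, m$tissue, "rep2")
        comb <- tryCatch(combineReplicates(repA, repB, config),
            error = function(e) stop(sprintf(
                "stage combine (%s, %s): %s", m$assay, m$tissue,
                conditionMessage(e))))
        combined[[m$assay]][[m$tissue]] <- comb
        writePeaksBed(comb, file.path(outDir, "combined",
            sprintf("%s_%s.bed", m$assay, m$tissue)))
        frags <- list(rep1 = readFrags(m$rep1Fragments, "rep1"),
                      rep2 = readFrags(m$rep2Fragments, "rep2"))
        row <- markSummary(comb, frags, genome)
        row$assay <- m$assay
        row$coveragePct <- round(row$coveragePct, 1L)
        metricRows[[i]] <- row[, c("assay", "mark", "tissue",
            "callerStyle", "nPeaks", "meanWidth", "medianWidth",
            "minWidth", "maxWidth", "coveragePct", "frip.rep1",
            "frip.rep2")]
    }
    metrics <- do.call(rbind, metricRows)
    .writeDf(metrics, file.path(outDir, "summary_metrics.tsv"))

    uniqRows <- list(); corRows <- list(); reports <- list()
    for (an in unique(manifest$assay)) {
        mm <- manifest[manifest$assay == an, ]
        panel <- TissuePanel(combined[[an]],
            usableReads = setNames(mm$usableReads, mm$tissue))
        rep <- uniquenessReport(panel)
        reports[[an]] <- rep
        uniqRows[[an]] <- cbind(assay = an, rep$perTissue,
            stringsAsFactors = FALSE)
        corRows[[an]] <- data.frame(assay = an,
            rTotalUnique = rep$rTotalUnique,
            rReadsTotal = rep$rReadsTotal,
            sharedFraction = rep$sharedFraction, stringsAsFactors = FALSE)
    }
    .writeDf(do.call(rbind, uniqRows),
        file.path(outDir, "uniqueness.tsv"))
    .writeDf(do.call(rbind, corRows),
        file.path(outDir, "panel_correlations.tsv"))

    annRows <- list(); tssRows <- list(); annDists <- list()
    for (an in unique(manifest$assay)) {
        style <- manifest$style[manifest$assay == an][1L]
        if (!style %in% annotateStyles) next
        for (t in names(combined[[an]])) {
            comb <- combined[[an]][[t]]
            if (length(comb) == 0L) next
            ann <- annotatePeaks(comb, index)
            .writeDf(ann, file.path(outDir, "annotation",
                sprintf("%s_%s.tsv", an, t)))
            dist <- annotationDistribution(comb, index)
            annDists[[an]][[t]] <- dist
            annRows[[length(annRows) + 1L]] <- data.frame(assay = an,
                tissue = t, category = names(dist),
                pct = round(as.numeric(dist), 2L),
                stringsAsFactors = FALSE)
            tss <- tssDistanceDistribution(comb, index)
            tssRows[[length(tssRows) + 1L]] <- data.frame(assay = an,
                tissue = t, bin = names(tss),
                pct = round(as.numeric(tss), 2L),
                stringsAsFactors = FALSE)
        }
    }
    .writeDf(do.call(rbind, annRows),
        file.path(outDir, "annotation_distribution.tsv"))
    .writeDf(do.call(rbind, tssRows),
        file.path(outDir, "tss_distance_distribution.tsv"))

    if (writeTracks) {
        for (i in seq_len(nrow(manifest))) {
            m <- manifest[i, ]
            input <- readFrags(m$inputFragments, "input")
            track <- combinedSignalTrack(
                readFrags(m$rep1Fragments, "rep1"),
                readFrags(m$rep2Fragments, "rep2"),
                input, input, genome, binSize)
            writeBedGraph(track, file.path(outDir, "tracks",
                sprintf("%s_%s.bedgraph", m$assay, m$tissue)))
        }
    }

    egf <- effectiveGenomeFraction(
        lapply(unique(manifest$inputFragments), readFrags,
            sample = "input"), genome)
    log <- c(
        sprintf("package\tChIPpanel %s", as.character(
            packageVersion("ChIPpanel"))),
        sprintf("bundle\t%s", basename(bundleDir)),
        sprintf("samples\t%d", nrow(manifest)),
        sprintf("feNarrow\t%g", config@feNarrow),
        sprintf("feBroad\t%g", config@feBroad),
        sprintf("mergeBookended\t%s", config@mergeBookended),
        sprintf("promoterWindow\t%d", promoterWindow),
        sprintf("downstreamWindow\t%d", downstreamWindow),
        sprintf("binSize\t%d", binSize),
        sprintf("effectiveGenomeFraction\t%.6f", egf))
    writeLines(log, file.path(outDir, "run_log.tsv"))
    invisible(list(combined = combined, metrics = metrics,
        uniqueness = reports, annotation = annDists,
        effectiveGenomeFraction = egf))
}

#' Recompute the reference summary tables
#'
#' From the vendored per-tissue reference tables of an eight-tissue
#' stallion histone ChIP-seq panel (genome coverage percentages,
#' tissue-unique peak percentages, and minimum usable reads with combined
#' peak counts), recomputes every derivable summary statistic — per-mark
#' mean combined peak counts, the coverage-average row, the Pearson
#' correlation of minimum usable reads vs combined peaks per mark, and
#' the total-vs-unique peak correlation per mark with unique counts
#' reconstructed as pct x total — and pairs each with the published
#' value.
#'
#' @return data.frame with columns \code{quantity}, \code{mark},
#'   \code{computed}, \code{published}.
#' @export
reproduceReferenceTables <- function() {
    dir <- system.file("extdata", "reference", package = "ChIPpanel",
        mustWork = TRUE)
    rd <- function(f) read.table(file.path(dir, f), sep = "\t",
        header = TRUE, check.names = FALSE, stringsAsFactors = FALSE)
    coverage <- rd("genome_coverage_pct.tsv")
    uniquePct <- rd("tissue_unique_pct.tsv")
    readsPeaks <- rd("reads_and_combined_peaks.tsv")
    published <- rd("published_summary.tsv")
    marks <- unique(readsPeaks$mark)
    rows <- list()
    add <- function(quantity, mark, computed) {
        pub <- published$value[published$quantity == quantity &
            published$mark == mark]
        rows[[length(rows) + 1L]] <<- data.frame(quantity = quantity,
            mark = mark, computed = computed,
            published = if (length(pub)) pub else NA_real_,
            stringsAsFactors = FALSE)
    }
    for (m in marks) {
        sub <- readsPeaks[readsPeaks$mark == m, ]
        add("meanCombinedPeaks", m, mean(sub$combinedPeaks))
        add("rReadsVsPeaks", m, pearsonR(sub$minUsableReads,
            sub$combinedPeaks))
    }
    for (cn in setdiff(names(coverage), "tissue"))
        add("avgCoveragePct", cn, mean(coverage[[cn]]))
    for (m in setdiff(names(uniquePct), "tissue")) {
        sub <- readsPeaks[readsPeaks$mark == m, ]
        total <- sub$combinedPeaks[match(uniquePct$tissue, sub$tissue)]
        stopifnot(!anyNA(total))
        uniq <- uniquePct[[m]] / 100 * total
        add("rTotalVsUnique", m, pearsonR(total, uniq))
    }
    do.call(rbind, rows)
}
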