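## Whole-study simulation and fixture-bundle serialization: every input
## the pipeline consumes, plus expected-outcome tables derived purely
## from the generator's planted labels (which truth peaks are concordant,
## their FE draws, and which tissues share each region) — never from the
## pipeline's own interval operations.

#' Simulate a complete multi-tissue study
#'
#' One deterministic random stream (seeded from the design) drives gene
#' models, truth peaks, replicates, fragments and input controls for
#' every assay and tissue, together with the expected combined and
#' tissue-unique peak counts implied by the planted labels.
#'
#' @param design a \code{SimulationDesign}.
#' @param config the \linkS4class{ValidationConfig} whose thresholds
#'   define "FE-passing" in the expected-outcome tables.
#' @return a list: \code{design}, \code{genome} (Seqinfo), \code{genes}
#'   (\linkS4class{GeneModels}), \code{inputs} (tissue -> input
#'   \linkS4class{FragmentSet}), \code{assays} (assay -> list with
#'   \code{spec}, \code{truth}, \code{reps}, \code{fragments},
#'   \code{usableReads}, \code{expected}).
#' @export
simulateStudy <- function(design, config = validationConfig()) {
    stopifnot(inherits(design, "SimulationDesign"))
    .withSeed(design$seed, .simulateStudy(design, config))
}

.simulateStudy <- function(design, config) {
    genome <- .designGenome(design)
    genes <- simulateGeneModels(genome, design$nGenes, seed = NULL)
    inputs <- lapply(design$tissues, function(t)
        simulateFragments(GRanges(), design$fragmentsPerSample, 0, genome,
            design$fragLen, sample = paste0("input_", t), seed = NULL))
    names(inputs) <- design$tissues
    assays <- list()
    for (an in names(design$assays)) {
        spec <- design$assays[[an]]
        tp <- .simulateTruthPeaks(design, an, spec)
        reps <- list(); frags <- list()
        usable <- numeric(0)
        for (t in design$tissues) {
            sim <- simulateReplicates(tp$truth[[t]], design,
                spec$feMeanlog, tp$noise[[t]]$repA, tp$noise[[t]]$repB,
                seed = NULL)
            nA <- as.integer(round(design$fragmentsPerSample *
                runif(1, 0.75, 1.25)))
            nB <- as.integer(round(design$fragmentsPerSample *
                runif(1, 0.75, 1.25)))
            frags[[t]] <- list(
                repA = simulateFragments(tp$truth[[t]], nA,
                    spec$targetFrip, genome, design$fragLen,
                    sample = sprintf("%s_%s_rep1", an, t), seed = NULL),
                repB = simulateFragments(tp$truth[[t]], nB,
                    spec$targetFrip, genome, design$fragLen,
                    sample = sprintf("%s_%s_rep2", an, t), seed = NULL))
            usable[t] <- min(nA, nB)
            reps[[t]] <- sim
        }
        assays[[an]] <- list(spec = spec, truth = tp$truth,
            regions = tp$regions, reps = reps, fragments = frags,
            usableReads = usable,
            expected = .expectedOutcomes(tp, reps, spec, design, config))
    }
    list(design = design, genome = genome, genes = genes,
        inputs = inputs, assays = assays)
}

## Expected combined/unique counts from planted labels only: a truth peak
## survives validation iff it is concordant and FE-passes in >= 1
## replicate; a surviving region is tissue-unique iff no other tissue's
## surviving peaks occupy its slot (unique-role always; shared-role iff
## it survives in exactly one tissue).
.expectedOutcomes <- function(tp, reps, spec, design, config) {
    thr <- .feThreshold(spec$style, config)
    survivors <- lapply(design$tissues, function(t) {
        ti <- reps[[t]]$truthInfo
        ti$truthId[ti$inA & ti$inB &
            ((!is.na(ti$feA) & ti$feA > thr) |
             (!is.na(ti$feB) & ti$feB > thr))]
    })
    names(survivors) <- design$tissues
    sharedIds <- tp$regions$truthId[tp$regions$role == "shared"]
    sharedSurvN <- table(factor(unlist(lapply(survivors, function(s)
        intersect(s, sharedIds))), levels = sharedIds))
    out <- lapply(design$tissues, function(t) {
        s <- survivors[[t]]
        sShared <- intersect(s, sharedIds)
        nUnique <- sum(!s %in% sharedIds) +
            sum(sharedSurvN[sShared] == 1L)
        data.frame(tissue = t, nCombined = length(s),
            nUnique = nUnique, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Write a self-contained fixture bundle
#'
#' Serializes a simulated study as the file tree the pipeline consumes:
#' \code{genome/chrom.sizes}, \code{genes/genes.gtf}, per-assay
#' narrowPeak/broadPeak replicate calls, per-replicate fragment BEDs,
#' per-tissue input BEDs, a \code{manifest.tsv} tying them together, and
#' \code{truth/} tables holding the planted region registry and the
#' expected combined/unique counts. Identical design and seed give a
#' byte-identical bundle.
#'
#' @param design a \code{SimulationDesign}.
#' @param outDir output directory (created).
#' @param config \linkS4class{ValidationConfig} for the expected-outcome
#'   tables.
#' @return invisibly, the simulated study list.
#' @export
writeFixtureBundle <- function(design, outDir,
                               config = validationConfig()) {
    study <- simulateStudy(design, config)
    for (d in c("", "genome", "genes", "peaks", "fragments", "truth"))
        dir.create(file.path(outDir, d), showWarnings = FALSE,
            recursive = TRUE)
    writeChromSizes(study$genome, file.path(outDir, "genome",
        "chrom.sizes"))
    writeGeneModelsGtf(study$genes, file.path(outDir, "genes",
        "genes.gtf"))
    manifest <- list()
    regions <- list()
    expected <- list()
    for (an in names(study$assays)) {
        a <- study$assays[[an]]
        ext <- if (a$spec$style == "narrow") "narrowPeak" else "broadPeak"
        writePeaks <- if (a$spec$style == "narrow") writeNarrowPeak else
            writeBroadPeak
        for (t in names(a$reps)) {
            base <- sprintf("%s_%s", an, t)
            p1 <- file.path("peaks", sprintf("%s_rep1.%s", base, ext))
            p2 <- file.path("peaks", sprintf("%s_rep2.%s", base, ext))
            f1 <- file.path("fragments", sprintf("%s_rep1.bed", base))
            f2 <- file.path("fragments", sprintf("%s_rep2.bed", base))
            writePeaks(a$reps[[t]]$repA, file.path(outDir, p1))
            writePeaks(a$reps[[t]]$repB, file.path(outDir, p2))
            writeFragmentsBed(a$fragments[[t]]$repA, file.path(outDir, f1))
            writeFragmentsBed(a$fragments[[t]]$repB, file.path(outDir, f2))
            manifest[[length(manifest) + 1L]] <- data.frame(
                assay = an, mark = a$spec$mark, style = a$spec$style,
                tissue = t, rep1Peaks = p1, rep2Peaks = p2,
                rep1Fragments = f1, rep2Fragments = f2,
                inputFragments = file.path("fragments",
                    sprintf("input_%s.bed", t)),
                usableReads = a$usableReads[[t]],
                stringsAsFactors = FALSE)
        }
        regions[[an]] <- cbind(assay = an, a$regions,
            stringsAsFactors = FALSE)
        expected[[an]] <- cbind(assay = an, a$expected,
            stringsAsFactors = FALSE)
    }
    for (t in names(study$inputs))
        writeFragmentsBed(study$inputs[[t]], file.path(outDir,
            "fragments", sprintf("input_%s.bed", t)))
    .writeDf(do.call(rbind, manifest), file.path(outDir, "manifest.tsv"))
    .writeDf(do.call(rbind, regions),
        file.path(outDir, "truth", "truth_regions.tsv"))
    .writeDf(do.call(rbind, expected),
        file.path(outDir, "truth", "expected_uniqueness.tsv"))
    invisible(study)
}

.writeDf <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = TRUE)
    invisible(path)
}
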