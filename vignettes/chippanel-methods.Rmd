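---
title: "ChIPpanel: methods and design notes"
author: "ChIPpanel authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ChIPpanel: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

ChIPpanel implements the downstream half of a histone-modification
ChIP-seq study: everything that happens *after* reads have been trimmed,
mapped, deduplicated, MAPQ-filtered and fed to a peak caller. Its inputs
are per-replicate peak calls (narrowPeak/broadPeak), usable fragments as
BED intervals (the deduplicated, quality-filtered read-pair proxies),
chromosome sizes, and transcript models (GTF or BED12). From these it
builds replicate-validated combined peak sets, quality metrics, tissue
panels, TSS-anchored annotations and input-subtracted signal tracks.
Read processing, alignment and the peak callers themselves are out of
scope: the package consumes their output formats, and its synthetic
generator emulates their output characteristics.

# Coordinate and overlap conventions

All conventions are fixed once, in the interval layer:

* Files use BED-style 0-based half-open coordinates; in memory
  everything is a 1-based closed `GRanges`. Conversion happens only in
  the readers and writers. GTF (1-based inclusive) is converted on read.
* "Overlap" always means at least one shared base. There is no
  minimum-fraction or reciprocal requirement anywhere, matching the
  default of the interval-intersection tooling this workflow
  standardizes on.
* Strand is ignored for all peak-peak and peak-fragment overlap; histone
  peaks are unstranded. Strand is honoured only in feature annotation
  (promoter and downstream windows, TSS distances).
* `mergeIntervals()` joins bookended (abutting) intervals by default,
  matching the merge tool's convention; whether the original workflow
  merged bookended replicate-validated peaks is not documented, so the
  behaviour is a flag (`mergeBookended`).

# Replicate validation

Each tissue/mark has two biological replicates. The combined peak set is
built as:

1. Filter each replicate's peaks to fold enrichment (FE) over input
   **strictly greater** than the threshold: 2.0 for narrow marks
   (H3K4me1, H3K4me3, H3K27ac), 1.5 for broad marks (H3K27me3). The
   wording "greater than" is read literally; an FE of exactly 2.0 fails.
2. Intersect the FE-filtered peaks of one replicate with *all called
   peaks* of the other replicate, keeping whole peak records (not
   clipped overlap fragments — the outputs are peaks). The alternative
   clipped behaviour is available via `clipToOverlap`.
3. Merge the validated records of both directions.

Every combined peak therefore passed the caller's FDR cutoff in both
replicates (membership in a replicate's call set certifies it; FDR is
not re-checked here) and exceeded the FE threshold in at least one. A
subtlety that the planted-truth tests pin down: when a peak's FE passes
in only one replicate, only that replicate's record enters the merged
interval; the other replicate supports the validation but does not
extend the peak. Combined peaks carry no scores — merging score columns
across replicates has no principled definition — only provenance counts
(`nRecordsA`, `nRecordsB`).

Empty replicate call sets produce a warning and an empty combined set
rather than an error, so a panel with one failed sample still runs.

# Metrics

* **FRiP** is the fraction of usable *fragments* (read-pair proxies, not
  individual mates) overlapping at least one peak, each fragment counted
  at most once. An empty fragment set is an error, not a zero.
* **Genome coverage** is 100 x distinct covered bases / genome length,
  reported at 1 decimal place in the pipeline tables.
* **Effective genome fraction** merges all input-control fragment sets
  and reports the covered fraction — the mappable-genome proxy passed to
  peak callers.
* **overlapFraction(a, b)** (share of a's peaks touching b) is
  deliberately asymmetric and partial-overlap based, while
  **nestingProfile** requires full containment; the pair separates "the
  two callers find the same regions" from "one island spans many narrow
  peaks".

# Tissue panels

A `TissuePanel` holds one mark's combined peak sets across tissues plus
the minimum usable reads across the two replicates per tissue (the
minimum, not the mean — the limiting replicate governs peak-calling
power). A peak is tissue-unique when it shares no base with any other
tissue's peaks for that mark. The report includes Pearson correlations
of total vs unique peak counts and of usable reads vs total counts; when
a correlation is undefined (constant vector, e.g. identical tissues), it
is reported as `NA` rather than aborting the report. For H3K27me3 the
pipeline keeps the narrow-style and island-style call sets as separate
assays, so uniqueness is computed per caller style.

# Feature annotation

Each peak is assigned exactly one category by the fixed priority
Promoter > 5' UTR > 3' UTR > Exon > Intron > Downstream > Distal
Intergenic, evaluated at a single anchor position. The anchor is the
peak midpoint by default — deterministic for both narrow and broad peaks
— with an option to use the summit where present. Windows: promoter =
TSS +/- 1000 bp (configurable), downstream = 300 bp past the transcript
3' end, both strand-aware and clipped at chromosome boundaries.

TSS sets are transcript-level. When several transcripts compete, the
winner is the one whose feature wins the priority contest, with ties
broken by (distance, chromosome, TSS, gene id, transcript id) — fully
deterministic. TSS distances are signed in gene orientation (negative =
upstream). The TSS-distance histogram uses unsigned distances with
default bins 0-1 kb, 1-3 kb, 3-5 kb, 5-10 kb, 10-100 kb, >100 kb; the
bin edges are configurable since the reference figures do not print
them.

Gene models carry exons but no CDS records, so the 5'/3' UTR categories
are structurally unreachable and their mass flows to Exon. The category
levels are kept in all outputs (with zero counts) so downstream scripts
see a stable schema. A gene-level TSS collapse is not implemented; with
one transcript per gene in the synthetic models the two coincide, and
this is a known limitation for multi-isoform annotations.

# Signal tracks

Tracks are built per sample as: bin fragment coverage on a fixed grid
(default 50 bp, a common track resolution; the bin size is a knob, not a
published value), scale the input control by the SES (signal extraction
scaling) factor, subtract, then average the two replicates' subtracted
tracks unweighted.

The SES factor orders bins by ascending sample signal (ties by bin
index), accumulates sample and control fractions along that ordering,
finds the split point maximizing (control fraction − sample fraction),
and returns cumulative sample counts / cumulative control counts there.
Two numerical choices are ours: candidate split points are restricted to
those with positive cumulative mass in both tracks (on sparse grids the
unrestricted maximum can sit inside the zero-sample prefix, where the
ratio degenerates to 0), and the *last* maximizer is taken on ties,
which makes `sesScaleFactor(x, x)` exactly 1. Negative post-subtraction
values are retained, never clipped — regions where scaled input exceeds
sample signal are information, and the bedGraph writer keeps them.

A caveat the tests respect: SES picks its split point from the
low-sample tail of the ordering, so at modest per-bin counts the factor
is conditionally biased slightly low and the background mean of a
subtracted track is near zero at the scale of single-bin noise, not at
the scale of the standard error of the mean. At sequencing-scale depths
this bias is negligible; at desk scale it is visible, which is why the
background-centred property is asserted against bin noise.

# The synthetic generator

`simulationDesign()` fixes the study conditions the package is tested
under; the defaults emulate the eight-tissue, two-stallion panel the
pipeline was built around, at desk scale:

* 3 chromosomes of 1 Mb (all downstream metrics are scale-free ratios,
  so genome size only affects runtime);
* four marks plus an island-style H3K27me3 variant, with mean peak
  widths 1360 / 1219 / 1535 / 1650 / 18466 bp (log-normal, log-sd 0.3);
* FE drawn log-normally with medians 3.0 (narrow) and 2.2 (broad) and
  log-sd 0.6, putting roughly a quarter of the mass below the 2.0 / 1.5
  thresholds so threshold behaviour is always exercised;
* replicate concordance 0.8 and coordinate jitter of up to 10% of the
  width per edge, a realistic level of replicate disagreement;
* a 16% per-tissue unique fraction (so 84% of peaks are shared by more
  than one tissue) drawn as disjoint planted regions;
* per-mark FRiP targets 0.46 / 0.32 / 0.65 / 0.30 / 0.47 and 200 bp
  fragments, matching the reference panel's medians and targeted
  fragment size.

The generator's central trick is slot allocation: all truth regions of
an assay — the shared pool, each tissue's unique peaks, and each
replicate's noise peaks — are laid out in disjoint slots separated by
gaps larger than the jitter extent. Distinct truth regions therefore
*cannot* come to overlap in any replicate, so planted quantities
(combined sets, uniqueness counts, nesting fractions, FRiP) are
recovered exactly, not approximately, and the acceptance properties are
deterministic given a seed. Fragment placement puts exactly
`floor(n x targetFrip)` fragments in peaks and rejects out-of-peak
draws that touch a peak.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: mapping artefacts and blacklist regions,
copy-number and accessibility biases in the input, FE values correlated
with peak width or position, overlapping truth regions between marks'
callers beyond the planted nesting, and any antibody- or
library-specific structure. The planted-truth recoveries validate the
*bookkeeping* of every stage exactly; they say nothing about caller
quality on real signal.

# Pipeline and reproducibility

`runPipeline()` consumes a fixture-bundle directory (a `manifest.tsv`
plus peaks/fragments/genome/genes files — `writeFixtureBundle()` writes
one) and emits combined peak BEDs, a summary-metrics table, uniqueness
and correlation tables, annotation distributions, bedGraph tracks and a
run log. Nothing in the outputs depends on time or environment, so a
re-run on the same inputs is byte-identical; the tests assert this
file-by-file. Problem sizes in the shipped tests and acceptance script
(2-8 tissues, 18-150 truth peaks per tissue, 300 kb - 1 Mb chromosomes,
500-10000 fragments per sample) were chosen to keep a full run in
seconds while leaving every code path exercised.

`reproduceReferenceTables()` recomputes, from vendored per-tissue
reference tables of the stallion panel, every summary statistic that is
derivable at desk scale: per-mark mean combined peak counts, the
genome-coverage average row, Pearson correlations of minimum usable
reads vs combined peaks, and total-vs-unique correlations with unique
counts reconstructed as percent x total. The reconstruction inherits
the rounding of the published percentages, which is why the recomputed
total-vs-unique correlations match to two-three decimals rather than
exactly; the genome-scale quantities themselves (per-tissue counts,
coverage, FRiP) require the original sequencing data and are validated
only as planted-truth properties on synthetic panels.

# Known limitations

* Exactly two replicates; no IDR or pseudo-replicate machinery.
* No BAM/CRAM input; fragments arrive as BED intervals.
* No bigWig output; tracks are bedGraph.
* UTR categories require CDS records the gene-model layer does not
  carry.
* The SES small-sample bias described above.
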