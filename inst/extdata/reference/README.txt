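Reference summary tables from an eight-tissue, two-replicate stallion
histone ChIP-seq panel (H3K4me1, H3K4me3, H3K27ac, H3K27me3; tissues:
adipose, brain, heart, lamina, liver, lung, muscle, testis), vendored so
reproduceReferenceTables() can recompute the derivable statistics offline:

genome_coverage_pct.tsv    per-tissue percent of the genome covered by
                           combined peaks; the H3K27me3 columns separate
                           narrow-style (-M) and island-style (-S) callers
tissue_unique_pct.tsv      percent of each tissue's combined peaks unique
                           to that tissue, per mark
reads_and_combined_peaks.tsv  minimum usable reads across the two
                           biological replicates and combined peak count,
                           per mark and tissue (minReadsReplicate names
                           the replicate with the fewer usable reads)
published_summary.tsv      the published values of the derivable summary
                           statistics, paired with recomputed values by
                           reproduceReferenceTables()
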