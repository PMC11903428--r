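quantity	mark	value
meanCombinedPeaks	H3K27ac	76778
meanCombinedPeaks	H3K4me1	120309
meanCombinedPeaks	H3K4me3	33969
meanCombinedPeaks	H3K27me3	158480
rReadsVsPeaks	H3K27ac	0.733
rReadsVsPeaks	H3K4me1	0.004
rReadsVsPeaks	H3K4me3	0.398
rReadsVsPeaks	H3K27me3	0.862
avgCoveragePct	H3K27ac	4.1
avgCoveragePct	H3K4me1	6.2
avgCoveragePct	H3K4me3	2.2
avgCoveragePct	H3K27me3-M	10.4
avgCoveragePct	H3K27me3-S	24.3
rTotalVsUnique	H3K27ac	0.778
rTotalVsUnique	H3K4me1	0.519
rTotalVsUnique	H3K4me3	0.923
rTotalVsUnique	H3K27me3	0.874
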