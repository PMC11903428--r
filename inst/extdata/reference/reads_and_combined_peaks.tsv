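mark	tissue	minReadsReplicate	minUsableReads	combinedPeaks
H3K27ac	adipose	AH3	11841844	57307
H3K27ac	brain	AH3	28767074	58463
H3K27ac	heart	AH4	28986609	89654
H3K27ac	lamina	AH3	23823796	81895
H3K27ac	liver	AH4	25056779	81759
H3K27ac	lung	AH4	26005392	90094
H3K27ac	muscle	AH3	16216664	47415
H3K27ac	testis	AH4	31632424	107633
H3K4me1	adipose	AH4	22976612	124995
H3K4me1	brain	AH4	33748599	103254
H3K4me1	heart	AH3	31026046	133481
H3K4me1	lamina	AH3	23743730	136805
H3K4me1	liver	AH4	28448813	124198
H3K4me1	lung	AH4	32876189	162224
H3K4me1	muscle	AH3	29981650	87973
H3K4me1	testis	AH4	27586751	89543
H3K4me3	adipose	AH3	28668914	41685
H3K4me3	brain	AH3	30245100	28804
H3K4me3	heart	AH4	32088317	33200
H3K4me3	lamina	AH4	17500964	26039
H3K4me3	liver	AH4	30318223	32603
H3K4me3	lung	AH3	32396228	33194
H3K4me3	muscle	AH3	19685919	25333
H3K4me3	testis	AH3	27740548	50893
H3K27me3	adipose	AH3	61352911	137696
H3K27me3	brain	AH3	51495389	87453
H3K27me3	heart	AH3	46128360	104207
H3K27me3	lamina	AH3	58482470	190940
H3K27me3	liver	AH3	68471421	265202
H3K27me3	lung	AH3	66585343	249506
H3K27me3	muscle	AH3	43455906	103055
H3K27me3	testis	AH3	44709318	129784
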