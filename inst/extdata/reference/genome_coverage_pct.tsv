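tissue	H3K27ac	H3K4me1	H3K4me3	H3K27me3-M	H3K27me3-S
adipose	3.5	8.4	2.8	13.9	27.0
brain	4.2	5.3	1.9	4.5	20.4
heart	4.9	7.6	2.0	12.0	26.2
lamina	4.1	5.7	1.6	11.3	24.0
liver	4.9	8.8	2.1	17.4	31.9
lung	4.4	7.9	2.0	11.2	24.4
muscle	3.5	3.8	1.7	5.2	21.9
testis	3.4	2.3	3.3	7.9	18.8
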