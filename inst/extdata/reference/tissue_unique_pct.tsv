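tissue	H3K27ac	H3K4me1	H3K4me3	H3K27me3
adipose	9.3	12.2	21.9	11.1
brain	33.3	26.7	13.6	12.5
heart	18.5	11.9	6.3	8.6
lamina	24.3	18.7	4.3	18.7
liver	24.5	22.2	17.7	37.3
lung	15.9	14.0	6.7	10.5
muscle	12.3	8.4	5.4	1.9
testis	28.4	12.1	47.0	12.1
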