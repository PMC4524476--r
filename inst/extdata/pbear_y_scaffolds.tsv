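scaffold_id	size_kb	ad_ratio	similar_y_genes
297	391	0.284	EIF1AY,KDM5D
309	317	0	DDX3Y,USP9Y,UTY
318	237	0.285	EIF2S3Y,KDM5D,USP9Y,ZFY
322	217	0.252	-
369	104	0.18	RBMY1A1
389	77	0.16	AMELY
393	70	0.12	-
403	63	0	UBA1Y
420	54	0	-
519	31	0.198	-
579	21	0.075	SRY
596	20	0	-
605	19	0	UBA1Y
613	18	0.158	-
632	16	0.205	-
646	15	0	EIF2S3Y
657	14	0	-
771	10	0.135	-
795	10	0	-
813	10	0	-
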