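# Multifoliolate QTL regions supported jointly by linkage mapping and BSR-seq
# bulks (V0 = shoot apical bud at true-leaf stage, V1 = first compound leaf).
# One row per detection-source interval; n_genes is the annotated overlapping
# gene count where printed. Coordinates are 1-based bp.
chrom	name	source	start	end	n_genes
Gm02	qMF-2-2	linkage	33000000	40350000	NA
Gm02	qMF-2-2	BSR-seq_V0	32820000	33960000	18
Gm02	qMF-2-2	BSR-seq_V0	34440000	35800000	12
Gm02	qMF-2-2	BSR-seq_V1	34610000	35900000	12
Gm04	qMF-4-2	linkage	9650000	44250000	NA
Gm04	qMF-4-2	BSR-seq_V1	28670000	30180000	13
Gm04	qMF-4-2	BSR-seq_V1	33460000	34500000	7
Gm04	qMF-4-2	BSR-seq_V1	35890000	36950000	5
Gm06	qMF-6	linkage	17300000	20700000	NA
Gm06	qMF-6	BSR-seq_V0	17560000	19470000	82
Gm12	qMF-12	linkage	12300000	20050000	NA
Gm12	qMF-12	BSR-seq_V1	11650000	12720000	9
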