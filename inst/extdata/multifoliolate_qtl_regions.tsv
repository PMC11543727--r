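# Confidence regions (common regions across biological replicates) of the ten
# QTLs for multifoliolate-leaf occurrence mapped in the C08 x W05 soybean RIL
# population; range_mb_printed is the range in Mb as printed in the source
# table, n_genes the annotated gene count (Wm82v4). Coordinates are 1-based bp.
# Note: the printed range of qMF-9 (0.85) disagrees with its printed bounds
# (which span 0.80 Mb); the bounds are retained verbatim.
name	replicates	chrom	start	end	range_mb_printed	n_genes
qMF-2-1	Rep1,Rep2,Rep3,BLUP	Gm02	5550000	5850000	0.3	44
qMF-2-2	Rep1,Rep3,BLUP	Gm02	33000000	40350000	7.35	154
qMF-4-1	BLUP	Gm04	0	2650000	2.65	336
qMF-4-2	Rep2,Rep3,BLUP	Gm04	9650000	44250000	34.6	641
qMF-5	BLUP	Gm05	29050000	36100000	7.05	601
qMF-6	Rep2,Rep3,BLUP	Gm06	17300000	20700000	3.4	138
qMF-9	Rep2,Rep3,BLUP	Gm09	5650000	6450000	0.85	1
qMF-12	Rep1,Rep2,Rep3,BLUP	Gm12	12300000	20050000	7.75	206
qMF-13	Rep2,Rep3,BLUP	Gm13	42800000	43350000	0.55	70
qMF-20	Rep1	Gm20	43200000	44750000	1.55	179
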