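# Curated result table (expression): probes with sex-specific smoking response
# in blood leukocytes, two European cohorts (NSHDS, EPIC-Italy); 143 current vs
# 311 never smokers; ranks are positions by ascending p-value among 29,667 probes
# in the sex-stratified current-vs-never analyses; effect size is the ratio of
# expression, current / never smokers, within each sex stratum.
# Curation notes:
#  - thousands separators removed from rank cells (ranks are integers)
#  - gene symbol for A_23_P120883 corrected from the printed "NMOX1" to HMOX1
#    (heme oxygenase 1), the symbol used throughout the source study's text
#  - missing gene symbols kept as NA
probe_id	gene_symbol	rank_m	rank_f	p_rank_diff	effect_m	effect_f
A_23_P120883	HMOX1	29411	31	2.82e-05	1.00	0.77
A_23_P87013	TAGLN	29013	74	3.86e-05	1.00	0.80
A_24_P410453	SYNE1	28573	120	5.42e-05	1.00	0.81
A_23_P23834	LGR6	27005	26	0.000146	1.49	0.72
A_23_P136347	EPS8	26954	16	0.00015	0.99	0.75
A_24_P173754	C1orf21	24586	24	0.000654	0.98	0.78
A_23_P354387	MYOF	24542	111	0.000706	0.98	0.79
A_23_P66881	RGS9	21736	118	0.00329	0.96	0.79
A_24_P76644	NA	20804	121	0.00524	0.98	0.88
A_23_P86682	MYOF	19999	56	0.00746	0.96	0.78
A_23_P43679	ZNF618	19852	22	0.00786	0.96	0.84
A_23_P1962	RARRES3	19775	113	0.00849	0.97	0.87
A_23_P113161	C1orf21	19632	47	0.0088	0.95	0.75
A_24_P921823	TCF7L2	18329	7	0.0153	0.96	0.77
A_23_P45831	CHD1L	19187	1428	0.0194	0.98	0.93
A_23_P48175	TMEM106C	18096	410	0.02	0.96	0.88
A_23_P39251	PLIN5	229	17725	0.0216	1.34	1.05
A_23_P200780	TGFBR3	17259	94	0.0247	0.94	0.80
A_23_P110791	CSF1R	16516	49	0.0323	0.95	0.80
A_32_P140475	KIAA1377	72	16014	0.0393	0.82	0.97
A_23_P213620	PPP2R2B	16049	256	0.0414	0.94	0.86
A_32_P75141	NA	15969	240	0.0424	0.94	0.85
A_23_P385105	PLCD4	15930	354	0.0448	0.94	0.86
A_24_P88763	LOXL3	15979	413	0.045	0.95	0.89
A_24_P9883	DKFZp761E198	27	15524	0.0461	1.49	1.05
A_23_P109171	BFSP1	15892	481	0.0475	0.93	0.84
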