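# Curated result table (methylation): CpG sites with sex-specific smoking
# response in blood leukocytes, two European cohorts (NSHDS, EPIC-Italy); ranks
# are positions by ascending p-value among 410,987 CpG sites in the
# sex-stratified current-vs-never analyses; beta columns are mean % methylation
# per smoking group within a sex stratum; delta_beta = beta_current - beta_never
# (percentage points); abs_delta_delta_beta = |delta_beta_f - delta_beta_m|.
# Curation notes:
#  - female-rank cells printed with a period plus three trailing digits (e.g.
#    "5.606") are thousands-separated integers and were normalised accordingly;
#    validated against the printed female median rank of 432
#  - the final column is defined as an absolute difference but is printed with
#    a sign in many rows; absolute values are stored
#  - missing gene symbols kept as NA
cpg_id	gene_symbol	rank_m	rank_f	p_rank_diff	beta_current_m	beta_never_m	delta_beta_m	beta_current_f	beta_never_f	delta_beta_f	abs_delta_delta_beta
cg03378003	SETD2	410615	375	1.73e-08	84.23	84.24	0.00	84.92	83.59	1.33	1.33
cg05713794	GP5	399753	108	4.17e-08	81.42	81.44	-0.02	80.63	78.46	2.17	2.19
cg13411554	CACNA1D	398828	206	4.53e-08	29.34	29.25	0.08	34.69	28.22	6.47	6.39
cg19028369	C3orf19	395672	613	6.06e-08	4.45	4.46	-0.01	4.29	4.59	-0.29	0.29
cg12611488	SKI	394498	63	6.38e-08	78.07	77.99	0.08	82.74	78.36	4.39	4.31
cg00436663	LOC400927	388154	171	1.07e-07	4.89	4.88	0.01	4.58	5.04	-0.45	0.47
cg17993335	DNMBP	387580	886	1.19e-07	79.14	79.20	-0.06	80.01	78.03	1.99	2.05
cg15743533	FAM110A	369751	234	4.5e-07	11.46	11.50	-0.04	10.67	11.72	-1.05	1.01
cg17098415	NA	366343	190	5.79e-07	1.83	1.84	-0.02	1.93	2.20	-0.27	0.25
cg17532753	HDAC4	370727	5606	6.26e-07	67.37	67.24	0.13	67.71	66.06	1.65	1.52
cg25115829	SUZ12P	179095	698	7.57e-07	73.04	72.23	0.81	75.55	72.97	2.58	1.77
cg13543915	NA	360064	247	9.28e-07	61.82	61.91	-0.09	62.91	64.51	-1.60	1.52
cg09257526	IL6R	359954	1607	1.03e-06	20.44	20.52	-0.08	20.04	20.67	-0.62	0.55
cg12689529	KIRREL3	341191	406	3.63e-06	6.84	6.91	-0.07	6.50	7.19	-0.69	0.62
cg13379236	EGF	332044	256	6.73e-06	60.43	60.24	0.19	62.51	60.67	1.84	1.65
cg06459104	EPB41L3	331586	341	6.98e-06	34.31	34.76	-0.46	33.82	38.07	-4.25	3.79
cg10232140	ERCC6	328904	141	8.25e-06	1.54	1.50	0.05	1.78	1.32	0.46	0.41
cg27430293	NA	152757	2427	8.33e-06	34.11	33.26	0.85	36.95	34.92	2.03	1.18
cg04985185	MBTPS1	321636	229	1.34e-05	83.83	83.59	0.24	84.90	82.76	2.14	1.89
cg27171474	CDCA8	329032	404	2.05e-05	84.89	84.78	0.11	86.22	85.01	1.21	1.09
cg08202265	TAC1	314885	272	2.09e-05	87.55	87.23	0.31	88.45	85.15	3.30	2.99
cg08528970	NA	311563	11616	5.23e-05	13.11	13.34	-0.22	13.88	14.30	-0.41	0.19
cg02003183	CDC42BPB	296555	442	6.59e-05	8.34	8.14	0.21	6.33	5.57	0.76	0.55
cg10665960	EPC2	295295	491	7.13e-05	4.71	4.66	0.05	4.57	4.90	-0.33	0.38
cg26724967	IL32	184670	577	9.65e-05	59.76	60.34	-0.58	59.95	61.77	-1.82	1.25
cg07411111	TPD52L2	289518	998	0.000104	61.46	61.04	0.42	62.07	59.99	2.08	1.66
cg09374353	EHD1	284155	321	0.000136	20.73	20.54	0.19	18.44	19.61	-1.18	1.37
cg23670519	NA	278212	616	0.000194	27.86	27.27	0.59	27.09	24.35	2.74	2.15
cg05307957	ARID1A	277497	132	0.000197	2.70	2.78	-0.08	2.99	3.38	-0.39	0.31
cg20305005	SCN2A	273040	240	0.000254	58.37	57.96	0.42	58.65	56.27	2.38	1.96
cg13989999	BCL2L1	268258	3290	0.000389	47.52	47.93	-0.41	48.03	49.34	-1.31	0.90
cg06397161	SYNGR1	262200	1787	0.000496	42.48	42.79	-0.31	44.56	46.19	-1.63	1.32
cg06959021	TCHP	255728	173	0.000639	58.68	58.28	0.40	61.71	59.85	1.86	1.45
cg01911191	NA	253223	1609	0.000782	2.70	2.62	0.08	2.34	2.07	0.27	0.19
cg25446789	DTNB	150180	257	0.000825	40.28	40.87	-0.60	40.07	42.21	-2.14	1.55
cg14179401	NA	249065	983	0.000935	33.38	33.60	-0.22	34.75	35.82	-1.07	0.85
cg08601457	FYN	242282	422	0.00127	7.11	7.28	-0.17	5.98	6.68	-0.70	0.53
cg16702313	C14orf43	239378	153	0.00145	60.71	61.00	-0.29	61.85	63.45	-1.60	1.31
cg13832372	LHX6	239227	188	0.00146	10.96	11.42	-0.45	10.32	12.60	-2.28	1.83
cg24242519	FAM49A	236302	1218	0.00177	13.47	13.75	-0.28	13.51	14.61	-1.10	0.82
cg22638542	SEC22C	227163	329	0.0026	80.69	80.38	0.31	82.48	81.37	1.11	0.80
cg01904243	C14orf43	225047	164	0.00284	13.97	14.22	-0.25	12.62	13.82	-1.20	0.95
cg06338710	GFI1	224461	205	0.00292	76.24	76.90	-0.66	77.50	79.53	-2.03	1.38
cg19048950	LOC100188	219307	463	0.00372	76.17	75.70	0.46	73.42	71.15	2.28	1.81
cg02104700	S100P	217731	496	0.004	2.42	2.49	-0.07	2.45	2.67	-0.22	0.15
cg15417641	CACNA1D	215584	77	0.00431	50.18	48.86	1.32	53.39	46.64	6.76	5.44
cg11222173	RPTOR	216169	1025	0.00438	62.03	61.49	0.54	61.00	58.74	2.26	1.71
cg08062087	C2orf66	215666	587	0.00439	69.15	68.61	0.54	70.09	68.06	2.03	1.49
cg14950321	PLIN5	215623	763	0.00444	39.87	40.42	-0.55	41.31	43.13	-1.82	1.27
cg08778287	IGF1R	214383	476	0.00462	33.41	32.78	0.64	31.37	28.84	2.54	1.90
cg13698937	C4orf46	210788	694	0.00545	76.64	75.97	0.67	77.47	75.32	2.15	1.49
cg00357551	FAM196B	207522	1016	0.00633	33.01	32.52	0.50	32.30	30.79	1.51	1.01
cg04359840	XYLT1	206167	346	0.00652	47.27	47.85	-0.58	47.80	49.99	-2.19	1.61
cg21698310	PPP1R9B	203847	822	0.00732	10.66	10.89	-0.23	9.69	10.49	-0.81	0.58
cg00816037	FAM38A	197944	281	0.0091	7.77	8.09	-0.33	6.69	7.77	-1.08	0.75
cg24488469	NA	192915	314	0.0111	15.97	16.30	-0.33	14.06	15.16	-1.09	0.76
cg12033822	SLC35C2	189184	1519	0.0134	26.76	27.15	-0.40	25.56	26.54	-0.98	0.58
cg22490254	NA	186085	396	0.0145	15.92	15.44	0.48	15.51	13.87	1.64	1.16
cg26840970	ZNF19	315231	309	0.0154	69.05	68.76	0.29	71.08	68.75	2.33	2.04
cg09608073	CHSY3	184657	712	0.0155	9.31	9.50	-0.19	7.99	8.47	-0.48	0.29
cg19925780	NA	179222	134	0.0185	57.36	56.05	1.30	59.58	56.04	3.54	2.24
cg25223634	C10orf26	172484	368	0.019	37.56	38.21	-0.64	35.14	37.58	-2.43	1.79
cg00026474	ST3GAL1	178373	842	0.0196	19.10	19.54	-0.44	19.23	20.63	-1.40	0.96
cg25114611	FKBP5	362777	198	0.0197	30.27	30.36	-0.08	30.44	31.81	-1.37	1.28
cg01609214	MIR30D	174169	418	0.0224	89.84	89.03	0.81	90.88	87.38	3.50	2.69
cg21188533	CACNA1D	173743	61	0.0224	43.74	41.82	1.91	52.19	43.74	8.45	6.54
cg06627354	TRPM8	173046	285	0.0232	65.91	65.21	0.70	64.45	61.66	2.79	2.10
cg25722983	STK40	290462	740	0.0236	45.26	45.55	-0.29	46.40	47.91	-1.52	1.22
cg25233339	ATP1B3	250770	212	0.0237	3.69	3.79	-0.10	3.03	3.48	-0.45	0.35
cg00449189	NA	171418	702	0.0249	12.06	12.39	-0.33	10.75	11.51	-0.77	0.44
cg08287903	UGT8	169875	180	0.0258	48.84	48.15	0.69	51.00	48.24	2.76	2.06
cg05055821	NA	168762	322	0.0269	9.90	9.65	0.26	9.44	8.67	0.77	0.52
cg05525812	NA	171414	3675	0.0276	16.95	17.39	-0.44	15.71	16.55	-0.84	0.40
cg20530056	IKBKE	168953	1699	0.028	63.75	64.26	-0.51	64.64	65.97	-1.33	0.82
cg01963224	NA	166963	102	0.0284	12.83	13.10	-0.28	11.88	12.94	-1.06	0.78
cg05548393	SLC30A8	165967	483	0.0298	77.09	76.22	0.87	78.67	76.30	2.37	1.50
cg24715767	PRDM2	165652	337	0.03	57.80	57.13	0.67	61.48	59.19	2.29	1.62
cg05603910	ANO9	167628	3304	0.031	78.58	77.55	1.03	75.77	73.98	1.79	0.77
cg16660971	RPTOR	163969	323	0.0317	72.09	71.01	1.08	71.01	66.95	4.06	2.98
cg06361984	NDE1	159841	809	0.0369	82.89	82.22	0.67	81.19	79.42	1.77	1.10
cg17873451	LOC440925	157993	231	0.0384	4.11	4.26	-0.15	3.54	3.90	-0.37	0.22
cg03220447	NAV2	159803	2277	0.0387	12.43	12.70	-0.27	12.44	12.97	-0.53	0.26
cg05756780	IL6R	156614	1147	0.0413	23.32	23.63	-0.31	22.65	23.65	-1.00	0.69
cg02104644	SYT7	158677	4255	0.0427	19.47	20.07	-0.59	18.63	19.87	-1.24	0.64
cg08242636	CBFB	155174	1149	0.0433	5.10	5.25	-0.15	5.00	5.37	-0.37	0.22
cg22006825	HNRNPUL1	171009	17624	0.0441	19.13	19.57	-0.45	19.20	19.75	-0.55	0.10
cg07201017	FLJ41350	159918	6965	0.0448	16.26	16.59	-0.33	15.82	16.34	-0.52	0.19
cg02571448	PCBP3	151595	974	0.0481	41.12	41.91	-0.79	41.66	43.59	-1.93	1.14
cg24968629	CELSR1	177517	192	0.0485	74.90	73.75	1.15	70.52	65.45	5.07	3.92
cg25474070	IL3	173116	895	0.0492	62.86	63.34	-0.47	64.15	65.74	-1.59	1.12
cg19859980	C1orf97	154094	4225	0.0492	2.51	2.60	-0.09	2.59	2.74	-0.15	0.06
cg03699074	FAM38A	150341	568	0.0494	14.23	14.69	-0.46	12.81	14.07	-1.26	0.79
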