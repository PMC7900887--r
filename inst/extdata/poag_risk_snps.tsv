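rsid	risk_allele	genotyped_directly	chrom	pos	reported_genes	odds_ratio	freq_afr	freq_eur
rs2472493	G	yes	9	104933567	ABCA1	1.31	0.311	0.418
rs4619890	G	yes	4	7851433	AFAP1	1.20	0.859	0.466
rs2276035	A	yes	11	120475651	ARHGEF12	1.18	0.251	0.164
rs7137828	T	no	12	111494996	ATXN2	1.17	0.981	0.536
exm-rs4236601	A	yes	7	116522675	CAV1, CAV2	1.27	0.399	0.259
rs4977756	A	yes	9	22068653	CDKN2B-AS1	1.48	0.68	0.6
rs9475699	A	yes	6	56437256	COL21A1-DST	1.04	0.228	0
rs56962872	G	no	3	186482434	CRYGS, LINC02052, TBCCD1	1.14	0.933	0.69
rs2073006	T	no	6	637465	EXOC2	1.16	0.045	0.131
rs2745572	A	no	6	1548134	FOXC1	1.22	0.85	0.636
seq-rs9913911	A	yes	17	10127866	GAS7	1.17	0.836	0.627
seq-rs11969985	G	yes	6	1922673	GMDS	1.31	0.741	0.851
rs56335522	G	no	2	212893510	IKZF2	1.18	0.904	0.878
rs2710323	T	yes	3	52781889	ITIH1	1.14	0.278	0.495
rs9530458	T	no	13	75675139	LMO7	1.148	0.359	0.527
rs6478746	G	no	9	126605119	LOC105376277, LMX1B	1.14	0.266	0.297
rs4918865	C	no	10	93183256	MYOF, XRCC6P1, CYP26A1, CYP26C1, EXOC6	1.119	0.635	0.594
rs9494457	T	no	6	136153656	PDE7B	1.08	0.629	0.633
rs10483727	T	yes	14	60606157	SIX6	1.32	0.966	0.404
rs4656461	G	yes	1	165717968	TMCO1	1.38	0.256	0.141
rs35934224	C	no	22	19885122	TXNRD2	1.28	0.691	0.846
rs2041895	C	no	12	106956310	TMEM263*	1.48	0.177	0.537
rs284491	T	no	8	104946405	None	1.52	0.719	0.659
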