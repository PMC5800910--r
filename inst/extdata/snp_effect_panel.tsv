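biomarker	rsid	chrom	position_bp	effect_allele	effect_allele_freq	allelic_effect	printed_allele	printed_allele_is_effect	xx_printed	ox_printed	oo_printed
AFP	rs12506899	4	74538147	T	0.33	1.08	T	TRUE	1.10	1.02	0.95
AFP	rs2251844	15	41623770	C	0.47	1.10	T	FALSE	0.92	1.00	1.11
CA19-9	rs17271883	19	5785212	G	0.44	1.29	A	FALSE	0.78	1.01	1.31
CA19-9	rs3760775	19	5792356	G	0.25	1.49	G	TRUE	1.76	1.18	0.79
CA19-9	rs265548	19	17763334	T	0.23	1.04	T	TRUE	1.07	1.02	0.98
CA19-9	rs1047781	19	53898443	T	0.40	1.38	A	FALSE	0.76	1.04	1.43
CEA	rs8176749	9	135121009	T	0.21	1.17	C	FALSE	0.93	1.09	1.28
CEA	rs8176720	9	135122694	C	0.45	1.08	T	FALSE	0.93	1.01	1.09
CEA	rs3670775	19	5792356	A	0.25	1.06	G	FALSE	0.97	1.03	1.09
CEA	rs1047781	19	53898443	T	0.40	1.17	A	FALSE	0.88	1.03	1.20
CEA	rs441810	21	41620777	G	0.18	1.01	A	FALSE	1.00	1.01	1.02
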