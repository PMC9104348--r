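feature_id	formula	annotation	adduct	mz_experimental	rt_min	mass_error_ppm	log2fc	q_value	confidence_level
78	C4H6O3	oxobutanoic acid	[M-H]-	101.0245	5.11	0.59	-0.36	0.03	2
92	C3H7NO3	serine	[M-H]-	104.0354	8.71	0.58	-0.23	0.03	2
159	C4H9NO3	threonine	[M-H]-	118.0509	8.35	-0.25	-0.23	0.03	2
242	C5H12N2O2	ornithine	[M-H]-	131.0827	8.85	0.77	-0.17	0.03	2
251	C4H6O5	malic acid	[M-H]-	133.0143	7.10	0.70	-0.47	0.03	2
345	C5H6O5	oxoglutaric acid	[M-H]-	145.0143	5.13	0.18	-0.28	0.04	2
539	C6H13N3O3	citrulline	[M-H]-	174.0883	8.85	-0.28	-0.17	0.03	2
635	C7H12N2O4	N-acetylglutamine	[M-H]-	187.0724	4.90	-0.09	0.26	0.04	2
698	C6H8O7	citric acid/isocitric acid	[M-H]-	191.0197	6.67	0.02	-0.23	0.03	2
807	C11H12N2O2	tryptophan	[M-H]-	203.0824	6.67	-0.76	-0.31	0.03	2
1742	C24H38O2	bile acids and derivatives	[M-H]-	357.2796	1.17	-0.69	0.54	0.03	2
1766	C20H30O6	hydroxy-12-oxo-eicosatrienedioic acid	[M-H]-	365.1966	1.19	-0.94	-0.44	0.02	2
1780	C24H38O3	bile acids and derivatives	[M-H]-	373.2744	1.20	-1.19	0.49	0.05	2
1807	C20H30O7	tetrahydroxy-12-oxo-tetraenoic acid	[M-H]-	381.1917	1.10	-0.51	-0.18	0.04	2
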