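feature_id	annotation	adduct	mz_experimental	formula	rt_min	log2fc	mass_error_ppm	confidence_level	lipid_class
3968	20alpha-hydroxyprogesterone	[M+H]+	317.2476	C21H32O2	1.35	0.90	0.32	2	sterol
2209	Cer(d41:1)	[M+CH3COOH-H]-	694.6365	C41H81NO3	7.36	0.12	1.40	2	Cer
96	citrulline	[M-H]-	174.0885	C6H13N3O3	1.02	-0.22	0.67	2	polar
473	FA(16:1)	[M-H]-	253.2174	C16H30O2	2.28	-0.01	0.49	2	FA
1253	FA(28:0)	[M-H]-	423.4209	C28H56O2	6.89	-0.36	0.39	2	FA
4628	LPC(0:0_18:2)	[M+H]+	520.3401	C26H50NO7P	1.77	-0.25	0.54	2	LPC
4738	LPC(20:4)	[M+H]+	544.3402	C28H50NO7P	1.81	-0.10	0.86	2	LPC
5068	LPC(24:2)	[M+H]+	604.4336	C32H62NO7P	2.77	0.09	-0.17	2	LPC
1257	LPE(O-15:0)	[M-H]-	424.2851	C20H44NO6P	2.28	-0.07	4.07	2	LPE
2668	PC(17:0_18:2)	[M+H2CO2-H]-	816.5782	C43H82NO8P	4.56	0.01	2.69	2	PC
7098	PC(41:6)	[M+H]+	848.6162	C49H86NO8P	5.22	0.05	-0.22	2	PC
5785	PC(O-16:0_18:2)	[M+H]+	744.5903	C42H82NO7P	5.34	-0.18	0.19	2	PC O-
6406	PC(O-38:2)	[M+H]+	800.6534	C46H90NO7P	6.55	-0.23	0.72	2	PC O-
2297	PE(34:0)	[M-H]-	718.5404	C39H78NO8P	6.18	0.07	1.71	2	PE
2475	PE(36:1)	[M-H]-	772.5873	C43H84NO8P	6.89	0.02	1.45	2	PE
2406	PE(17:0_20:4)	[M-H]-	752.5243	C42H76NO8P	5.00	-0.16	1.01	2	PE
5982	PE(18:0_20:4)	[M+H]+	768.5545	C43H78NO8P	5.24	-0.13	0.89	2	PE
7279	PI(18:0_18:2)	[M+H]+	863.5644	C45H83O13P	4.56	-0.17	0.03	2	PI
2543	SM(d36:1)	[M+H]+	731.6069	C41H83N2O6P	4.87	-0.16	0.95	2	SM
2733	SM(d40:2)	[M+H2CO2-H]-	829.6458	C45H89N2O6P	6.20	-0.13	2.21	2	SM
7627	TG(53:2)	[M+NH4]+	890.818	C56H104O6	9.08	-0.45	0.91	2	TG
8173	TG(18:1_18:1_20:4)	[M+NH4]+	924.8022	C59H102O6	8.30	-0.19	0.71	2	TG
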