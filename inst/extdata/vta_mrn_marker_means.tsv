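gene	segment	HPC	HPT	STR	MRN	VTA	tsi_published
Tlcd1	VTA	214.57	142.88	20.74	15.01	473.22	0.55
Loxl2	VTA	1.03	1.10	1.21	0.86	16.00	0.79
Dbh	VTA	0.29	0.05	0.01	3.89	16.42	0.79
Crh	MRN	0.79	1.99	0.40	21.17	4.96	0.72
Pde12	MRN	13.72	3.24	16.88	81.78	3.52	0.69
Actr5	MRN	2.89	3.63	3.58	97.07	2.84	0.88
Fam210a	MRN	52.14	3.66	3.16	102.94	4.00	0.62
Rtl1	MRN	2.05	6.46	4.55	152.14	3.21	0.90
Slc6a5	shared	0.03	0.04	0.03	84.86	31.97	1.00
Mab21l2	shared	0.09	0.51	0.08	21.92	10.34	0.98
Rln3	shared	0.03	0.26	0.05	29.45	14.85	0.99
Glra1	shared	0.08	8.29	0.36	85.35	51.80	0.94
Lamp5	shared	12.31	6.15	37.59	144.49	53.47	0.78
Nefh	shared	18.10	26.01	16.10	299.94	220.86	0.90
Nefl	shared	206.83	145.48	137.48	820.72	684.99	0.75
Nefm	shared	66.62	57.71	73.11	598.01	507.12	0.85
Cplx1	shared	234.47	113.82	284.92	778.27	555.21	0.68
Fth1	shared	2170.92	1536.80	2882.29	4405.25	3310.33	0.54
Atp1a3	shared	778.55	768.97	592.48	1293.45	1000.71	0.52
Mbp	shared	1033.04	1080.91	2797.41	4590.89	3633.36	0.63
Snap25	shared	715.33	501.60	502.25	1307.61	1046.86	0.58
Ckb	shared	505.70	650.24	1216.06	1329.61	1084.69	0.50
Gnas	shared	634.95	1184.41	315.21	1345.01	1113.15	0.54
Slc6a9	shared	14.11061	50.1118	28.1854	110.2638	88.92087	0.68
Tph2	shared	0.296341	0.084168	0.20817	11.80536	16.09617	0.98
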