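property	description	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
GEIM800101	Alpha-helix indices (Geisow-Roberts, 1980)	1.29	1	0.81	1.1	0.79	1.07	1.49	0.63	1.33	1.05	1.31	1.33	1.54	1.13	0.63	0.78	0.77	1.18	0.71	0.81
PONP800108	Average number of surrounding residues (Ponnuswamy et al., 1980)	6.05	5.7	5.04	4.95	7.86	5.45	5.1	6.16	5.8	7.51	7.37	4.88	6.39	6.62	5.65	5.53	5.81	6.98	6.73	7.62
CHOP780202	Normalized frequency of beta-sheet (Chou-Fasman, 1978b)	0.83	0.93	0.89	0.54	1.19	1.1	0.37	0.75	0.87	1.6	1.3	0.74	1.05	1.38	0.55	0.75	1.19	1.37	1.47	1.7
ZIMJ680102	Bulkiness (Zimmerman et al., 1968)	11.5	14.28	12.82	11.68	13.46	14.45	13.57	3.4	13.69	21.4	21.4	15.71	16.25	19.8	17.43	9.47	15.77	21.67	18.03	21.57
WEBA780101	RF value in high salt chromatography (Weber-Lacey, 1978)	0.89	0.88	0.89	0.87	0.85	0.82	0.84	0.92	0.83	0.76	0.73	0.97	0.74	0.52	0.82	0.96	0.92	0.2	0.49	0.85
NAGK730103	Normalized frequency of coil (Nagano, 1973)	0.72	1.33	1.38	1.04	1.01	0.81	0.75	1.35	0.76	0.8	0.63	0.84	0.62	0.58	1.43	1.34	1.03	0.87	1.35	0.83
GRAR740101	Composition (Grantham, 1974)	0	0.65	1.33	1.38	2.75	0.89	0.92	0.74	0.58	0	0	0.33	0	0	0.39	1.42	0.71	0.13	0.2	0
FINA770101	Helix-coil equilibrium constant (Finkelstein-Ptitsyn, 1977)	1.08	1.05	0.85	0.85	0.95	0.95	1.15	0.55	1	1.05	1.25	1.15	1.15	1.1	0.71	0.75	0.75	1.1	1.1	0.95
KYTJ820101	Hydropathy index (Kyte-Doolittle, 1982)	1.8	-4.5	-3.5	-3.5	2.5	-3.5	-3.5	-0.4	-3.2	4.5	3.8	-3.9	1.9	2.8	-1.6	-0.8	-0.7	-0.9	-1.3	4.2
ZIMJ680104	Isoelectric point (Zimmerman et al., 1968)	6	10.76	5.41	2.77	5.05	5.65	3.22	5.97	7.59	6.02	5.98	9.74	5.74	5.48	6.3	5.68	5.66	5.89	5.66	5.96
OOBM770103	Long range non-bonded energy per atom (Oobatake-Ooi, 1977)	-0.491	-0.554	-0.382	-0.356	-0.67	-0.405	-0.371	-0.534	-0.54	-0.762	-0.65	-0.3	-0.659	-0.729	-0.463	-0.455	-0.515	-0.839	-0.656	-0.728
GRAR740103	Volume (Grantham, 1974)	31	124	56	54	55	85	83	3	96	111	111	119	105	132	32.5	32	61	170	136	84
FASG760101	Molecular weight (Fasman, 1976)	89.09	174.2	132.12	133.1	121.15	146.15	147.13	75.07	155.16	131.17	131.17	146.19	149.21	165.19	115.13	105.09	119.12	204.24	181.19	117.15
COHE430101	Partial specific volume (Cohn-Edsall, 1943)	0.75	0.7	0.61	0.6	0.61	0.67	0.66	0.64	0.67	0.9	0.9	0.82	0.75	0.77	0.76	0.68	0.7	0.74	0.71	0.86
WOEC730101	Polar requirement (Woese, 1973)	7	9.1	10	13	5.5	8.6	12.5	7.9	8.4	4.9	4.9	10.1	5.3	5	6.6	7.5	6.6	5.3	5.7	5.6
GRAR740102	Polarity (Grantham, 1974)	8.1	10.5	11.6	13	5.5	10.5	12.3	9	10.4	5.2	4.9	11.3	5.7	5.2	8	9.2	8.6	5.4	6.2	5.9
CHOP780205	Normalized frequency of C-terminal helix (Chou-Fasman, 1978b)	1.2	1.25	0.59	0.61	1.11	1.22	1.24	0.42	1.77	0.98	1.13	1.83	1.57	1.1	0	0.96	0.75	0.4	0.73	1.25
CHOP780204	Normalized frequency of N-terminal helix (Chou-Fasman, 1978b)	1.29	0.44	0.81	2.02	0.66	1.22	2.44	0.76	0.73	0.67	0.58	0.66	0.71	0.61	2.01	0.74	1.08	1.47	0.68	0.61
MCMT640101	Refractivity (McMeekin et al., 1964), Cited by Jones (1975)	4.34	26.66	13.28	12	35.77	17.56	17.26	0	21.81	19.06	18.78	21.29	21.64	29.4	10.93	6.35	11.01	42.53	31.53	13.92
OOBM770102	Short and medium range non-bonded energy per atom (Oobatake-Ooi, 1977)	-1.404	-0.921	-1.178	-1.162	-1.365	-1.116	-1.163	-1.364	-1.215	-1.189	-1.315	-1.074	-1.303	-1.135	-1.236	-1.297	-1.252	-1.03	-1.03	-1.254
PONP800101	Surrounding hydrophobicity in folded form (Ponnuswamy et al., 1980)	12.28	11.49	11	10.97	14.93	11.28	11.19	12.01	12.84	14.77	14.1	10.8	14.33	13.43	11.19	11.26	11.65	12.95	13.29	15.07
BULH740101	Transfer free energy to surface (Bull-Breese, 1974)	-0.2	-0.12	0.08	-0.2	-0.45	0.16	-0.3	0	-0.12	-2.26	-2.46	-0.35	-1.47	-2.33	-0.98	-0.39	-0.52	-2.01	-2.24	-1.56
CHOP780101	Normalized frequency of beta-turn (Chou-Fasman, 1978a)	0.66	0.95	1.56	1.46	1.19	0.98	0.74	1.56	0.95	0.47	0.59	1.01	0.6	0.6	1.52	1.43	0.96	0.96	1.14	0.5
EISD840101	Consensus normalized hydrophobicity scale (Eisenberg, 1984)	0.25	-1.76	-0.64	-0.72	0.04	-0.69	-0.62	0.16	-0.4	0.73	0.53	-1.1	0.26	0.61	-0.07	-0.26	-0.18	0.37	0.02	0.54
HOPT810101	Hydrophilicity value (Hopp-Woods, 1981)	-0.5	3	0.2	3	-1	0.2	3	0	-0.5	-1.8	-1.8	3	-1.3	-2.5	0	0.3	-0.4	-3.4	-2.3	-1.5
JANJ780101	Average accessible surface area (Janin et al., 1978)	27.8	94.7	60.1	60.6	15.5	68.7	68.2	24.5	50.7	22.8	27.6	103	33.5	25.5	51.5	42	45	34.7	55.2	23.7
CHAM820101	Polarizability parameter (Charton-Charton, 1982)	0.046	0.291	0.134	0.105	0.128	0.18	0.151	0	0.23	0.186	0.186	0.219	0.221	0.29	0.131	0.062	0.108	0.409	0.298	0.14
FAUJ880103	Normalized van der Waals volume (Fauchere et al., 1988)	1	6.13	2.95	2.78	2.43	3.95	3.78	0	4.66	4	4	4.77	4.43	5.89	2.72	1.6	2.6	8.08	6.47	3
KLEP840101	Net charge (Klein et al., 1984)	0	1	0	-1	0	0	-1	0	0	0	0	1	0	0	0	0	0	0	0	0
BHAR880101	Average flexibility indices (Bhaskaran-Ponnuswamy, 1988)	0.357	0.529	0.463	0.511	0.346	0.493	0.497	0.544	0.323	0.462	0.365	0.466	0.295	0.314	0.509	0.507	0.444	0.305	0.42	0.386
ZIMJ680103	Polarity (Zimmerman et al., 1968)	0	52	3.38	49.7	1.48	3.53	49.9	0	51.6	0.13	0.13	49.5	1.43	0.35	1.58	1.67	1.66	2.1	1.61	0.13
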