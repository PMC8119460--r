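branch	gene	n_taxa	stat	df	p_printed	p_bonferroni_printed	omega2a	omega2b	sites
ancestral_bird	ABCG5	75	5.32	1	0.021	0.042	998.99	998.99	135S, 290T, 483S
ancestral_bird	AGPAT1	40	74.72	1	5.424E-18	1.084E-17	155.38	155.38	14I, 183R^
ancestral_bird	AGPAT2	90	4.02	1	0.045	0.090	14.66	14.66	31C^, 116M
ancestral_bird	APOA1	50	5.86	1	0.015	0.031	998.99	998.99	126Q^
ancestral_bird	APOA4	41	9.06	1	0.003	0.005	334.64	334.64	25D, 49A, 64D, 79K, 92V^, 97K, 126R, 133A, 144T, 156K, 158E, 162Q^, 180S, 224S, 233Q, 247K, 255Q, 270L^, 277K, 288S, 295G, 319N, 362L, 365I
ancestral_bird	APOB	69	11.99	1	0.001	0.001	10.51	10.51	84S, 248A, 981E, 1704A, 1926Q, 3722N, 4514Y
ancestral_bird	ATP1B3	83	10.56	1	0.001	0.002	37.99	37.99	60N^, 95L, 120L^
ancestral_bird	ATP1B4	84	6.36	1	0.012	0.023	998.99	998.99	22K, 29A, 30K^, 103I, 135K, 188T^
ancestral_bird	CD36	77	4.58	1	0.032	0.065	29.60	29.60	75M, 246N, 250I^, 292E, 371S
ancestral_bird	CELA3B	15	4.98	1	0.026	0.026	998.93	998.93	87D, 182I^, 199A
ancestral_bird	HK3	48	14.52	1	0.000	0.000	520.78	520.78	57I, 61Q, 88Q, 115C^, 296D, 362P, 522A^, 528E, 609I, 726R
ancestral_bird	LCT	71	15.20	1	9.670E-05	1.934E-04	999.00	999.00	251Q, 1790T, 1810S
ancestral_bird	NPC1L1	34	6.06	1	0.014	0.028	697.54	697.54	3S, 10L, 12F, 17F, 53Y, 83V, 93S, 94S^, 95W, 107G, 112L, 120S, 125Y^, 127Y, 157L
ancestral_bird	SI	46	25.78	1	3.826E-07	7.653E-07	218.16	218.16	69V, 178V, 309-, 347-, 382L, 923A, 1057G^, 1204Y^, 1291W^, 1292G, 1297Y^, 1432Y, 1453S^, 1535F^, 1663-, 1707H^
ancestral_bird	SLC2A5	28	10.16	1	0.001	0.001	18.45	18.45	85L, 93F, 108S^, 222E, 250A, 264S^, 342-, 355A, 411S^, 440A, 459G
ancestral_bird	SLC36A1	15	10.00	1	0.002	0.002	222.64	222.64	20S, 112P, 171E^, 212T, 215R^, 308T, 334S, 430S^
ancestral_bird	SLC5A1	67	3.92	1	0.048	0.095	19.29	19.29	470S^
ancestral_archosaur	ACE2	76	5.06	1	0.024	0.049	53.65	53.65	114Q, 142P, 181S^, 641Y, 699E, 712N, 797T
ancestral_archosaur	APOA4	41	4.92	1	0.027	0.053	44.66	44.66	192Q, 265L, 310V, 339E
ancestral_archosaur	APOB	69	7.76	1	0.005	0.011	13.97	13.97	401A, 1151D, 1171N^, 1625E, 1687D^, 1791Y, 2354K, 4096H
ancestral_archosaur	ATP1B4	84	14.16	1	0.000	0.000	139.31	139.31	6A, 43Q^, 45M, 153D, 186Y^, 193S
ancestral_archosaur	CEL	66	14.64	1	0.000	0.000	151.47	151.47	5-, 11-, 97E, 154K, 293V, 345G, 383Y
ancestral_archosaur	CPB1	51	10.62	1	0.001	0.002	998.99	998.99	142S, 143K^, 195R, 293N, 409I
ancestral_archosaur	DPP4	86	8.26	1	0.004	0.008	39.05	39.05	76A, 166S, 286L, 293F^
ancestral_archosaur	HKDC1	86	5.56	1	0.018	0.037	47.15	47.15	434V, 474H, 820N^
ancestral_archosaur	MEP1A	71	3.92	1	0.048	0.095	30.69	30.69	229*, 311I^, 373Q, 644-
ancestral_archosaur	MEP1B	84	6.20	1	0.013	0.026	111.71	111.71	346T
ancestral_archosaur	MME	90	7.46	1	0.006	0.013	540.88	540.88	94K, 375Y, 446Q^, 499D
ancestral_archosaur	MTTP	89	4.38	1	0.036	0.073	26.96	26.96	28I, 43L, 49G, 51S, 127W, 183N, 207L, 548F, 578L, 784V, 889E^
ancestral_archosaur	SCARB1	90	5.54	1	0.019	0.037	210.06	210.06	206S
ancestral_archosaur	SI	46	7.78	1	0.005	0.011	64.88	64.88	66E, 208V, 335-, 398S^, 607V, 650S, 1342Y
ancestral_archosaur	SLC15A1	76	21.38	1	3.767E-06	7.534E-06	613.86	613.86	320H, 484T, 514Y, 568A
ancestral_archosaur	SLC27A4	85	6.06	1	0.014	0.028	22.11	22.11	43R, 153A, 170G, 268S^, 349K, 397K^, 433Q, 475E, 563L
ancestral_archosaur	XPNPEP2	65	9.90	1	0.002	0.003	198.45	198.45	30I, 66Q^, 144D^
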