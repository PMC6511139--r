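scheme	category	n_candidates	enrichment	ci_low	ci_high	threshold
FOUR	high	19	0.017	-0.00013	0.034	NA
FOUR	moderate	391	4.40	3.84	4.96	6.88e-9
FOUR	low	799	245.45	236.44	254.45	3.84e-7
FOUR	other	102214	0.89	0.88	0.89	NA
FIVE	high	19	4.92	0.18	9.65	5.87e-9
FIVE	moderate	391	5.04	4.13	5.96	6.00e-9
FIVE	low	799	405.08	362.29	447.88	4.82e-7
FIVE	OC	7227	2.49	2.33	2.65	2.96e-9
FIVE	NKF	94987	0.72	0.70	0.74	NA
EIGHT	high	19	33.69	16.85	50.54	1.02e-7
EIGHT	moderate	391	17.16	13.56	20.75	5.20e-8
EIGHT	low	799	7.30	4.74	9.87	2.21e-8
EIGHT	UTR	343	16.64	12.56	20.43	5.04e-8
EIGHT	OC	7152	3.59	3.30	3.89	1.09e-8
EIGHT	RE	9520	2.53	2.33	2.73	7.65e-9
EIGHT	ncRNA	95	22.70	15.27	30.12	6.88e-8
EIGHT	NKI	85104	0.53	0.51	0.55	NA
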