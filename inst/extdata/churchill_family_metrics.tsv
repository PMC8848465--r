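family	n_bins_regional	n_bins_local	pct_local	n_seqs_regional	n_seqs_local	habitat	adult_diet	larval_diet	nri	p_nri	nti	p_nti
Buprestidae	87	3	4	470	3	terrestrial	phytophagous	phytophagous	2.04	0.038	2.2	0.05
Cantharidae	101	6	6	5043	23	terrestrial	predaceous	predaceous	2.68	0.001	2.54	0.007
Carabidae	418	20	5	3642	90	terrestrial	predaceous	predaceous	1.57	0.05	2.47	0.013
Chrysomelidae	264	5	2	3805	71	terrestrial	phytophagous	phytophagous	-0.69	0.75	-0.38	0.63
Coccinellidae	108	4	5	2481	9	terrestrial	predaceous	predaceous	-0.13	0.57	-0.65	0.75
Cryptophagidae	68	3	5	428	5	terrestrial	fungivorous	fungivorous	0.95	0.15	1.73	0.05
Curculionidae	364	8	2	7453	11	terrestrial	phytophagous	phytophagous	0.16	0.45	0.51	0.27
Dytiscidae	120	36	43	1531	140	aquatic	predaceous	predaceous	1.52	0.07	1.45	0.07
Elateridae	251	5	2	3035	20	terrestrial	phytophagous	phytophagous	0.35	0.38	-0.23	0.55
Gyrinidae	25	7	39	215	22	aquatic	predaceous	predaceous	2.15	0.03	1.39	0.09
Haliplidae	15	6	67	75	6	aquatic	phytophagous	phytophagous	2.19	0.02	1.07	0.16
Hydrophilidae	62	6	11	265	13	aquatic	phytophagous	predaceous	0.74	0.22	2.26	0.02
Latridiidae	83	3	4	4216	11	terrestrial	fungivorous	fungivorous	-0.96	0.83	-0.98	0.85
Leiodidae	129	5	4	593	19	terrestrial	fungivorous	fungivorous	1.03	0.15	0.79	0.21
Scirtidae	46	3	7	2881	9	aquatic	phytophagous	phytophagous	0.65	0.22	0.36	0.28
Staphylinidae	972	21	2	7187	35	terrestrial	predaceous	predaceous	0.2	0.43	1.46	0.08
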