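family	n_bins_regional	n_bins_local	pct_local	n_seqs_regional	n_seqs_local	habitat	adult_diet	larval_diet	nri	p_nri	nti	p_nti
Buprestidae	45	3	7	159	3	terrestrial	phytophagous	phytophagous	2.1	0.03	2.55	0.03
Cantharidae	59	6	10	1483	23	terrestrial	predaceous	predaceous	2.19	0.002	2.05	0.01
Carabidae	212	20	9	1702	90	terrestrial	predaceous	predaceous	-0.02	0.5	1.5	0.07
Chrysomelidae	199	5	3	2903	71	terrestrial	phytophagous	phytophagous	-0.39	0.64	-0.19	0.53
Coccinellidae	70	4	6	1113	9	terrestrial	predaceous	predaceous	-0.56	0.7	-0.89	0.83
Cryptophagidae	34	3	9	203	5	terrestrial	fungivorous	fungivorous	1.14	0.11	1.73	0.06
Curculionidae	204	8	4	3711	11	terrestrial	phytophagous	phytophagous	-1.01	0.86	-0.37	0.6
Dytiscidae	51	36	71	1368	140	aquatic	predaceous	predaceous	2.08	0.01	1.59	0.05
Elateridae	141	5	4	1092	20	terrestrial	phytophagous	phytophagous	0.03	0.49	-0.56	0.7
Gyrinidae	11	7	64	178	22	aquatic	predaceous	predaceous	2.7	0.02	1.36	0.08
Haliplidae	7	6	86	61	6	aquatic	phytophagous	phytophagous	1.91	0.04	1.2	0.13
Hydrophilidae	40	6	15	191	13	aquatic	phytophagous	predaceous	1.02	0.15	2.84	0.007
Latridiidae	52	3	6	2252	11	terrestrial	fungivorous	fungivorous	-0.14	0.5	-0.19	0.55
Leiodidae	68	5	7	293	19	terrestrial	fungivorous	fungivorous	1.01	0.15	0.5	0.28
Scirtidae	32	3	9	1734	9	aquatic	phytophagous	phytophagous	0.49	0.26	0.21	0.32
Staphylinidae	485	31	6	2509	35	terrestrial	predaceous	predaceous	1.37	0.08	2.32	0.008
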