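accession	description	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
MITS020101	Amphiphilicity index (Mitaku et al., 2002)	0	0	0	1.27	0	0	1.45	0	3.67	0	0	0	0	1.25	2.45	0	0	0	6.93	5.06
QIAN880113	Weights for alpha-helix at the window position of 6 (Qian-Sejnowski, 1988)	-0.08	-0.25	-0.24	-0.19	0	-0.1	0.29	-0.01	0.45	0.28	0.11	-0.08	-0.42	-0.28	0.05	0.07	-0.33	-0.13	0.36	0
JOND750101	Hydrophobicity (Jones, 1975)	0.87	1.52	0.66	0.67	2.87	0.1	0.87	3.15	1.64	2.17	1.67	0.09	2.77	0	0.85	0.07	0.07	1.87	3.77	2.67
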