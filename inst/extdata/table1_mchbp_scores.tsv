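rank	coformer	delta
1	pyrazine	0.38
2	3-methylpyridine	0.36
3	theophylline	0.08
4	imidazole	0.07
5	2-amino-5-methylbenzoic_acid	0.06
6	ferulic_acid	0.06
7	apigenin	0.05
8	ketoglutaric_acid	0.05
9	4-aminobenzoic_acid	0.03
10	EDTA	0.03
11	ethylparaben	0.02
12	hesperetin	0.02
13	propylparaben	0.02
14	d-pantothenol	0.01
15	methylparaben	0.01
16	glutaric_acid	0.01
17	glycolic_acid	0.01
18	l-mandelic_acid	0.01
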