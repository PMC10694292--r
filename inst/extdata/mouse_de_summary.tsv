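gene_symbol	log2fc	fdr
Abcc3	1.69	3.28e-9
Abcc4	3.95	9.07e-19
Cyp1a2	-1.69	4.07e-7
Cyp2c29	-1.92	1.01e-9
Cyp2d22	-0.18	0.23
Cyp3a11	0.30	0.46
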