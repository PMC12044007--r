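snp_id	motif	allele1	allele2	p_allele1	p_allele2	fold_printed
rs13303327	ELF1	G	A	2.27e-3	1.28e-4	17.74
rs13303327	ELF2	G	A	2.08e-3	8.70e-5	23.91
rs13303327	ELF3	G	A	1.81e-3	1.31e-4	13.83
rs13303327	ELF5	G	A	6.56e-4	2.66e-5	24.64
rs13303160	FOSB	G	A	1.18e-4	2.93e-5	40.11
rs13303160	FOS	G	A	5.73e-4	2.74e-5	20.86
rs13303160	FOSL1	G	A	4.32e-4	4.94e-6	87.31
rs13303160	FOSL2	G	A	8.16e-4	2.15e-5	37.93
rs13303160	JUNB	G	A	8.00e-4	2.47e-5	32.36
rs13303160	JUND	G	A	9.47e-4	2.28e-5	41.63
rs13303160	JUN	G	A	8.40e-4	2.68e-5	31.37
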