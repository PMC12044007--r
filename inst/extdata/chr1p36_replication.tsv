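label	or	ci_low	ci_high	p	n_case	n_control	maf_case	maf_control
pandora	1.45	1.33	1.57	6.0e-10	2497	4611	0.14	0.10
ukbiobank	1.42	1.21	1.65	1.05e-5	1066	9399	0.12	0.09
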