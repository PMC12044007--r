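label	or	ci_low	ci_high	p	n_case	n_control
meta2018	1.20	1.12	1.29	7.3e-7	9040	12496
ukbiobank	1.42	1.21	1.65	1.05e-5	1066	9399
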