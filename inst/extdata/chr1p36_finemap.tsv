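variant_id	chrom	pos	or	ci_low	ci_high	p	r2_printed	llr_printed	pip_printed
rs13303010	1	894573	1.24	1.16	1.32	2.09e-10	1.00	1.00	0.27
rs3935066	1	900730	1.25	1.17	1.35	2.74e-10	0.89	1.30	0.22
rs113491766	1	895755	0.81	0.76	0.86	2.85e-10	1.00	1.35	0.20
rs13303327	1	895706	1.24	1.16	1.32	3.38e-10	1.00	1.60	0.18
rs10465241	1	886817	1.24	1.16	1.32	1.03e-9	0.90	4.74	0.06
rs10465242	1	886788	1.23	1.15	1.32	2.23e-9	0.90	10.07	0.03
rs13303160	1	901559	1.23	1.15	1.32	2.74e-9	0.93	12.31	0.02
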