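motif	system	pct_jewish	pct_non_jewish	chi_square	df	p
LMH	y	2.9	1.4	144.6	6	0.000
eLMH	y	1.8	0.2	431.2	5	0.000
CMH	y	6.5	0.7	1343.2	9	0.000
eCMH	y	1.5	0.0	686.2	3	0.000
GAL	y	0.7	1.4	50.5	6	0.000
IP	y	0.0	0.1	2.5	2	0.289
K1	mt	0.9	0.0	278.2	2	0.000
K2	mt	1.4	0.1	353.4	3	0.000
K3	mt	1.8	1.2	97.7	3	0.000
N	mt	1.2	0.0	395.0	2	0.000
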