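motif	system	group	total	typed	predicted
LMH	y	jewish	155	32	123
LMH	y	non_jewish	807	98	709
eLMH	y	jewish	93	NA	NA
eLMH	y	non_jewish	107	13	94
CMH	y	jewish	343	270	73
CMH	y	non_jewish	419	92	327
eCMH	y	jewish	81	64	17
eCMH	y	non_jewish	17	5	12
GAL	y	jewish	36	1	35
GAL	y	non_jewish	794	150	644
IP	y	jewish	0	0	0
IP	y	non_jewish	46	4	42
K1	mt	jewish	47	NA	NA
K1	mt	non_jewish	21	NA	NA
K2	mt	jewish	74	NA	NA
K2	mt	non_jewish	57	NA	NA
K3	mt	jewish	93	NA	NA
K3	mt	non_jewish	686	NA	NA
N	mt	jewish	63	NA	NA
N	mt	non_jewish	25	NA	NA
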