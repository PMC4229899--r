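motif	haplogroup	jewish	non_jewish
K1	K	29	15
K1	K1a9	18	6
K2	K	41	38
K2	K1a1b1a	33	17
K2	K1a3a3	0	1
K2	K2b1	0	1
K3	K	56	369
K3	K1a	0	2
K3	K1a1	1	3
K3	K1a14	0	1
K3	K1a16	0	3
K3	K1a19	1	4
K3	K1a1a	0	3
K3	K1a1a1	0	2
K3	K1a1a2	0	4
K3	K1a1a2a1	0	3
K3	K1a1b1	0	4
K3	K1a1b1b	0	5
K3	K1a1b1e	0	4
K3	K1a1b2a	0	1
K3	K1a2	0	2
K3	K1a2a	0	4
K3	K1a2b	0	2
K3	K1a2c	1	0
K3	K1a3	0	4
K3	K1a3a	0	5
K3	K1a3a3	0	3
K3	K1a3a4	0	3
K3	K1a4	0	2
K3	K1a4a1	3	22
K3	K1a4a1a	0	3
K3	K1a4a1a1	0	1
K3	K1a4a1a3	0	3
K3	K1a4a1a-T195C!	0	10
K3	K1a4a1b	0	1
K3	K1a4a1b1	0	3
K3	K1a4a1c	1	3
K3	K1a4a1d	0	3
K3	K1a4a1f	1	3
K3	K1a4b	0	1
K3	K1a4d	0	1
K3	K1a-T195C!	1	8
K3	K1b1c	0	1
K3	K1b2a	0	8
K3	K1b2a1	1	7
K3	K1b2a1a	1	2
K3	K1b2a2	1	4
K3	K1b2a2a	0	7
K3	K1b2b	0	12
K3	K1c1	1	25
K3	K1c1b	1	13
K3	K1c1c	2	18
K3	K1c1d	0	3
K3	K1c1f	0	7
K3	K2a	1	16
K3	K2a10	2	3
K3	K2a2a1	18	12
K3	K2a3	0	6
K3	K2a5	0	3
K3	K2a5a	0	1
K3	K2a6	0	28
K3	K2a7	0	3
K3	K2a9	0	3
K3	K2b1	0	9
N	N1b	40	18
N	N1b2	23	7
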