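motif	haplogroup	jewish	non_jewish
LMH	R1a-M198	79	400
LMH	R1a-M417	56	234
LMH	R1-Z280	0	35
LMH	R1a-L260	0	28
LMH	R1a-CTS6	8	3
LMH	R1a-L1029	0	12
LMH	R1a-L342/L657	5	5
LMH	R1a-Z93	1	4
LMH	R1a-SRY10831	1	7
LMH	R1a-Z287	1	4
LMH	R1a-CTS11962	1	14
LMH	R1a-CTS3402	1	19
LMH	R1a-CTS3412	1	1
LMH	R1b-M269	0	1
LMH	R1b-L23	1	0
LMH	R1b-P311	0	0
LMH	R-others	0	35
LMH	others	0	5
eLMH	R1a-M198/M17/M512	39	36
eLMH	R1a-M417/458	39	45
eLMH	R1-Z280	0	13
eLMH	R1a-L260	0	1
eLMH	R1a-CTS6	8	2
eLMH	R1a-L342/L657	5	3
eLMH	R1a-Z93	1	0
eLMH	R1a-CTS3402	0	6
eLMH	R1a-CTS3412	0	1
eLMH	R1b-L23	1	0
CMH	J-M304	1	1
CMH	J1-M267	196	236
CMH	J1-L147	13	8
CMH	J1-P58	16	18
CMH	J1-YSC0000076	6	16
CMH	J1-YSC0000234	4	4
CMH	J1-Z640/Z644	10	24
CMH	J1-PF4678	1	0
CMH	J1-PF4843	1	0
CMH	J1-ZS227	1	0
CMH	J1-F450	2	0
CMH	J1-CTS11741	1	2
CMH	J2-M172	67	74
CMH	J2-M67	8	16
CMH	J2-L210	6	8
CMH	J2-L25	1	1
CMH	J2-L26	2	0
CMH	J2-Z474	1	1
CMH	J2-Z482	1	0
CMH	J2-M410	0	1
CMH	J-others	0	5
CMH	R1a-M417/458	0	1
CMH	R1b-M269	1	0
CMH	R1b-L23	1	0
CMH	R1b-P311	2	0
CMH	R-others	0	1
CMH	others	1	2
eCMH	J1-M267	71	12
eCMH	J1-L147	4	0
eCMH	J1-P58	2	2
eCMH	J1-YSC0000234	2	1
eCMH	J1-CTS11741	0	2
eCMH	R1b-P311	2	0
GAL	J-M304	0	2
GAL	J1-M267	24	414
GAL	J1-L147	0	12
GAL	J1-P58	10	21
GAL	J1-YSC0000076	1	0
GAL	J1-L222	0	252
GAL	J2-M172	1	41
GAL	J2-L26	0	4
GAL	J2-M410	0	1
GAL	J-others	0	40
GAL	R1a-M198/M17/M512	0	1
GAL	R1b-M269	0	1
GAL	R1b-P311	0	1
GAL	R-others	0	2
GAL	others	0	2
IP	J1-M267	0	37
IP	J1-P58	0	1
IP	J1-L222	0	5
IP	J2-M172	0	1
IP	J-others	0	2
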