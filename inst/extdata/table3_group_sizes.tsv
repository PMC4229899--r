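system	group	n	n_hg_typed	n_hg_predicted
y	jewish	5281	1103	4178
y	non_jewish	57639	5593	51332
mt	jewish	2818	NA	NA
mt	non_jewish	27651	NA	NA
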