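sample_id	unclassified	Sphingomonas	Gp6
A1	30.91	3.41	10.74
A3	28.84	14.73	6.66
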