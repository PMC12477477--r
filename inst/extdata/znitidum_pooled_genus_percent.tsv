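group	unclassified	Sphingomonas	Gp6	Gp1	Spartobacteria_genera_incertae_sedis	Gp2	Erwinia	Povallibacter	Subdivision3_genera_incertae_sedis	Bradyrhizobium	Lacibacterium	Lysobacter	Pantoea	Rudaea	Gemmatimonas
A1/A3	29.875	9.07	8.7	0.405	1.355	0.24	0.095	2.34	1.485	0.91	1.42	2.445	0.005	0.035	1.41
A2/B1	24.295	0.88	0.845	9.9	5.66	7.785	0.01	4.005	3.58	2.055	0.02	0.01	0.005	0.29	1.245
B2/B3	19.635	10.105	1.17	2.75	2.11	2.55	7.37	0.655	1.815	2.025	0.035	0.215	6.1	2.12	1.915
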