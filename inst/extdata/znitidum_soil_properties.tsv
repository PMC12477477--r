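sample_id	pH	ORM	HT	CP	SP	SSG
A1	7.7	54.45	96	593.11	192.84	214.05
A2	4.3	35.48	125	462.05	318.13	219.83
A3	6.2	33.54	4	278.05	523.05	198.90
B1	4.3	39.52	56	492.00	298.59	209.41
B2	5.3	33.98	24	424.69	353.74	221.58
B3	5.5	9.55	353	443.08	356.83	200.10
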