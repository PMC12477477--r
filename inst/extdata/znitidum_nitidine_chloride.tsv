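group	nitidine_chloride_percent
A1/A3	0.205
A2/B1	0.25
B2/B3	0.87
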