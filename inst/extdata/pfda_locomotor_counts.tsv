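true	WH	BWH	TJ	AJ	AQ
WH	12	5	8	0	1
BWH	6	16	6	1	4
TJ	6	6	51	3	0
AJ	1	4	5	19	1
AQ	1	3	0	0	5
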