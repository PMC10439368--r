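true	WH	BWH	TJ	AJ	AQ
WH	14	6	5	0	1
BWH	6	20	6	0	1
TJ	3	1	60	2	0
AJ	0	0	1	29	0
AQ	1	2	2	0	4
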