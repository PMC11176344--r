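group	unit	total
Group1	CAG	4960
Group1	CCG	1511
Group1	CGG	1602
Group1	CTG	3518
Group1	GCC	1882
Group2	CAG	423
Group2	CCG	196
Group2	CGG	204
Group2	CTG	211
Group2	GCC	223
Group3	CAG	121
Group3	CCG	54
Group3	CGG	40
Group3	CTG	67
Group3	GCC	57
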