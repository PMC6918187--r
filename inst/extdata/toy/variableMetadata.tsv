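variableMetadata	mz	rt	annotation
F1	180.0634	120.0	glucose-like
F2	181.0667	120.5	unknown
F3	202.0453	121.0	unknown
F4	250.1000	400.0	unknown
F5	300.1000	123.0	unknown
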