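similarity	F1	F2	F3	F4	F5
F1	1	1	1	-1	0.993399
F2	1	1	1	-1	0.993399
F3	1	1	1	-1	0.993399
F4	-1	-1	-1	1	-0.993399
F5	0.993399	0.993399	0.993399	-0.993399	1
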