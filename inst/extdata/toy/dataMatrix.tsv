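dataMatrix	S1	S2	S3
F1	1000	2000	3000
F2	110	220	330
F3	500	1000	1500
F4	3000	2000	1000
F5	900	2100	2900
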