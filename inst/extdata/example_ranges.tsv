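taxon	A	B	C
t1	1	0	0
t2	1	0	0
t3	0	1	0
t4	0	0	1
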