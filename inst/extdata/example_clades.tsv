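clade	tip
cherry	t1
cherry	t2
core	t1
core	t3
all	t1
all	t4
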