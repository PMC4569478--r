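(((t1:1,t2:1):1,t3:2):1,t4:3);
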