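axis	metric	baseline	reranked
BP	P0	0.48	0.63
BP	P5	0.28	0.35
D	P0	0.48	0.59
D	P5	0.17	0.22
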