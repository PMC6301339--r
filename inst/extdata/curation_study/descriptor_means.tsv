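axis	system_mean	curator_mean	common_mean
BP	6.2	2.4	1.1
D	6.0	1.5	1.2
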