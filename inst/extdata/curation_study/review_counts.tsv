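axis	accepted	modified	rejected
BP	699	413	2061
D	1094	146	3727
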