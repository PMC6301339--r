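axis	both_accept	both_reject	split
BP	162	39	41
D	152	48	42
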