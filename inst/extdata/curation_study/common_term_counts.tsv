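axis	n_abstracts	n_with_common
BP	45	42
D	51	48
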