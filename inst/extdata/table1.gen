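2112
1011
1022
2011
2101
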