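hope_probability,outcome
0.007,died
0.034,died
0.036,died
0.147,died
0.336,died
0.439,died
0.553,died
0.814,died
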