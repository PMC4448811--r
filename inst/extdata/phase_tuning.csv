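value,probability
0,0.17
45,0.08
90,0.17
135,0.08
180,0.17
225,0.08
270,0.17
315,0.08
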