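value,probability
0,0.16
15,0.08
30,0.06
45,0.06
60,0.06
75,0.08
90,0.16
105,0.08
120,0.06
135,0.06
150,0.06
165,0.08
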