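value,probability
0.35,0.005
0.5,0.015
0.7,0.03
1,0.06
1.4,0.1
2,0.16
2.8,0.17
4,0.16
5.7,0.13
8,0.11
11.3,0.06
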