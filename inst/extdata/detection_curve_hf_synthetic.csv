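"month","cumulative"
0,0
3,0.0158
6,0.1336
9,0.2025
12,0.2514
15,0.2894
18,0.3204
21,0.3466
24,0.3693
27,0.3893
30,0.4072
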