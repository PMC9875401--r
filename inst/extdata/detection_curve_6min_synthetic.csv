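"month","cumulative"
0,0
3,0.0453
6,0.1527
9,0.2156
12,0.2602
15,0.2947
18,0.323
21,0.3469
24,0.3676
27,0.3859
30,0.4022
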