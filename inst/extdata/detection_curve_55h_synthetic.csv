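"month","cumulative"
0,0
3,0.0226
6,0.0764
9,0.1078
12,0.1301
15,0.1474
18,0.1615
21,0.1735
24,0.1838
27,0.1929
30,0.2011
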