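"age","qx"
50,0.004968
51,0.00528
52,0.005625
53,0.006007
54,0.006428
55,0.006894
56,0.007409
57,0.007977
58,0.008606
59,0.009301
60,0.010069
61,0.010917
62,0.011855
63,0.012891
64,0.014037
65,0.015303
66,0.016702
67,0.018248
68,0.019957
69,0.021845
70,0.023933
71,0.026239
72,0.028789
73,0.031606
74,0.03472
75,0.038161
76,0.041964
77,0.046167
78,0.050812
79,0.055946
80,0.061619
81,0.067889
82,0.074819
83,0.082477
84,0.090941
85,0.100295
86,0.110633
87,0.122058
88,0.134685
89,0.148639
90,0.164062
91,0.181106
92,0.199943
93,0.22076
94,0.243768
95,0.269195
96,0.297296
97,0.328352
98,0.362675
99,0.400607
100,1
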