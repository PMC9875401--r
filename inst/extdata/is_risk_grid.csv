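"chads2","noaf_none","noaf_aspirin","subaf_none","subaf_aspirin","subaf_noac","subaf_warfarin"
0,0.002,0.002,0.006,0.004,0.002,0.001
1,0.006,0.005,0.016,0.011,0.004,0.004
2,0.013,0.009,0.032,0.023,0.009,0.008
3,0.025,0.018,0.062,0.044,0.017,0.016
4,0.032,0.023,0.079,0.056,0.021,0.021
5,0.036,0.026,0.09,0.063,0.024,0.023
6,0.04,0.029,0.101,0.071,0.027,0.026
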