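drug_b,0.2,0.5,0.7,0.8,0.9,0.95
0.2,0.19,0.22,0.25,0.28,0.31,0.34
0.5,0.205,0.235,0.265,0.295,0.325,0.355
0.7,0.22,0.25,0.28,0.31,0.34,0.37
0.8,0.235,0.265,0.295,0.325,0.355,0.385
0.9,0.25,0.28,0.31,0.34,0.37,0.4
0.95,0.265,0.295,0.325,0.355,0.385,0.415
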