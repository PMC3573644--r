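drug_b,0.2,0.5,0.7,0.8,0.9,0.95
0.2,0.02,0.1,0.2,0.3,0.35,0.45
0.5,0.06,0.14,0.24,0.34,0.39,0.49
0.7,0.12,0.2,0.3,0.4,0.45,0.55
0.8,0.17,0.25,0.35,0.45,0.5,0.6
0.9,0.22,0.3,0.4,0.5,0.6,0.7
0.95,0.3,0.38,0.48,0.58,0.68,0.78
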