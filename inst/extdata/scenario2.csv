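drug_b,0.2,0.5,0.7,0.8,0.9,0.95
0.2,0.02,0.03,0.06,0.1,0.18,0.23
0.5,0.03,0.05,0.09,0.13,0.21,0.3
0.7,0.06,0.09,0.14,0.18,0.3,0.45
0.8,0.11,0.14,0.18,0.3,0.45,0.5
0.9,0.18,0.21,0.3,0.45,0.5,0.55
0.95,0.23,0.3,0.45,0.5,0.55,0.6
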