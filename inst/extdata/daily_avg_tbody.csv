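day,avg_tbody_c,alert
1,36.82,0
2,36.70,0
3,36.70,0
4,36.45,0
5,36.70,0
6,36.58,0
7,36.33,0
8,36.70,0
9,36.78,0
10,36.33,0
11,36.69,0
12,36.45,0
13,36.58,0
14,36.33,0
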