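# Synthetic background-mortality life table (all-population, ages 65-100).
# Gompertz emulation q(age) = min(1, 0.013 * exp(0.0935 * (age - 65))) of a
# recent US period life table; order of magnitude matches the published
# table at ages 65 (~0.013) and 100 (~0.35). NOT transcribed published data.
# Generated by crlmcea::synthetic_lifetable(0.013, 0.0935, 65:100).
age,qx
65,0.0130000000000000
66,0.0142741378434369
67,0.0156731547056490
68,0.0172092900546112
69,0.0188959829559391
70,0.0207479896461776
71,0.0227815126295185
72,0.0250143424273650
73,0.0274660132208569
74,0.0301579737480132
75,0.0331137749506071
76,0.0363592760124241
77,0.0399228705914546
78,0.0438357352252397
79,0.0481321020825749
80,0.0528495584477731
81,0.0580293755575607
82,0.0637168696674760
83,0.0699617985066043
84,0.0768187965890790
85,0.0843478531907273
86,0.0926148371724938
87,0.1016920732421261
88,0.1116589746956145
89,0.1226027381740026
90,0.1346191065137320
91,0.1478132063644095
92,0.1623004679019974
93,0.1782076346836473
94,0.1956738724790175
95,0.2148519867788146
96,0.2359097596320830
97,0.2590314175077245
98,0.2844192430220087
99,0.3122953446324714
100,0.3429035997805790
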