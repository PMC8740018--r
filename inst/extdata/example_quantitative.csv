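result
20
ND
300
45
ND
150
1200
80
ND
25
560
90
ND
40
ND
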