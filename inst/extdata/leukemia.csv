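time,wbc,ag
65,0.23,1
156,0.075,1
100,0.43,1
134,0.26,1
16,0.6,1
108,1.05,1
121,1,1
4,1.7,1
39,0.54,1
143,0.7,1
56,0.94,1
26,3.2,1
22,3.5,1
1,10,1
1,10,1
5,5.2,1
65,10,1
56,0.44,0
65,0.3,0
17,0.4,0
7,0.15,0
16,0.9,0
22,0.53,0
3,1,0
4,1.9,0
2,2.7,0
3,2.8,0
8,3.1,0
4,2.6,0
3,2.1,0
30,7.9,0
4,10,0
43,10,0
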