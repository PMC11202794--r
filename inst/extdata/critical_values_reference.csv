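n,alpha_0.01,alpha_0.05,alpha_0.1,alpha_0.2
10,0.350,0.250,0.250,0.150
11,0.364,0.273,0.273,0.182
12,0.375,0.292,0.208,0.208
13,0.308,0.231,0.231,0.154
14,0.321,0.250,0.179,0.179
15,0.333,0.267,0.200,0.133
16,0.281,0.219,0.219,0.156
17,0.294,0.235,0.176,0.176
18,0.306,0.194,0.194,0.139
19,0.263,0.211,0.158,0.158
20,0.275,0.225,0.175,0.125
21,0.286,0.190,0.190,0.143
22,0.250,0.205,0.159,0.114
23,0.261,0.217,0.174,0.130
24,0.229,0.188,0.146,0.146
25,0.240,0.200,0.160,0.120
26,0.250,0.173,0.173,0.135
27,0.222,0.185,0.148,0.111
28,0.232,0.196,0.161,0.125
29,0.241,0.172,0.138,0.103
30,0.217,0.183,0.150,0.117
31,0.226,0.161,0.129,0.097
32,0.234,0.172,0.141,0.109
33,0.212,0.152,0.152,0.121
34,0.221,0.162,0.132,0.103
35,0.200,0.171,0.143,0.114
36,0.208,0.153,0.125,0.097
37,0.216,0.162,0.135,0.108
38,0.197,0.145,0.118,0.092
39,0.205,0.154,0.128,0.103
40,0.188,0.163,0.138,0.088
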