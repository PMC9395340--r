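frame,right,left
1,0.100000,0.100000
2,0.100000,0.100000
3,0.100000,0.100000
4,0.100000,0.100000
5,0.100000,0.100000
6,0.100000,0.100000
7,0.100000,0.100000
8,0.100000,0.100000
9,0.103000,0.104000
10,0.106000,0.109000
11,0.109000,0.114000
12,0.112000,0.118000
13,0.114000,0.121000
14,0.116000,0.123000
15,0.117500,0.125000
16,0.119000,0.127000
17,0.120500,0.129000
18,0.122000,0.131000
19,0.123500,0.133000
20,0.125000,0.135000
21,0.126500,0.145000
22,0.128000,0.159666
23,0.129500,0.174332
24,0.134500,0.188998
25,0.144324,0.203664
26,0.154148,0.218330
27,0.163972,0.214330
28,0.173796,0.211330
29,0.183620,0.209330
30,0.180620,0.212330
31,0.178620,0.215330
32,0.177620,0.218330
33,0.179620,0.221330
34,0.181620,0.220330
35,0.183620,0.219330
36,0.185620,0.218330
37,0.184620,0.217330
38,0.183620,0.216330
39,0.182620,0.215330
40,0.181620,0.214330
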