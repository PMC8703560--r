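hour,price_cents_per_kwh
0,7.2
1,6.8
2,6.5
3,6.4
4,6.6
5,7.4
6,9.1
7,11.8
8,13.6
9,14.9
10,16.2
11,17.4
12,18.1
13,17.6
14,16.3
15,15.1
16,15.8
17,18.4
18,20.6
19,21.3
20,19.2
21,15.4
22,11.2
23,8.6
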