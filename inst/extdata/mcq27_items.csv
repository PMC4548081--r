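item,ss_amount,ss_delay,ll_amount,ll_delay
1,54,0,55,117
2,55,0,75,61
3,19,0,25,53
4,31,0,85,7
5,14,0,25,19
6,47,0,50,160
7,15,0,35,13
8,25,0,60,14
9,78,0,80,162
10,40,0,55,62
11,11,0,30,7
12,67,0,75,119
13,34,0,35,186
14,27,0,50,21
15,69,0,85,91
16,49,0,60,89
17,80,0,85,157
18,24,0,35,29
19,33,0,80,14
20,28,0,30,179
21,34,0,50,30
22,25,0,30,80
23,41,0,75,20
24,54,0,60,111
25,54,0,80,30
26,22,0,25,136
27,20,0,55,7
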