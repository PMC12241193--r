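# fireCN case-table v1
case_id,age,sex,cn_right,cn_left,cohb_right,cohb_left,scn_right,scn_left
1,89,F,2.0,3.7,79,94,2.2,2.1
2,78,M,1.7,2.9,13,14,1.7,1.4
3,69,F,ND,Trace,65,77,3.1,3.6
4,73,M,0.64,0.67,46,46,2.0,2.1
5,70,M,0.58,2.7,38,42,2.6,1.5
6,56,F,Trace,0.80,57,49,2.8,2.5
7,65,M,1.2,1.7,68,69,3.2,2.8
8,60,M,ND,ND,9.2,10,5.3,5.0
9,79,M,1.1,11,66,72,4.5,2.4
10,71,M,2.3,4.0,18,18,2.8,2.3
11,71,M,Trace,0.86,91,96,1.6,1.3
12,69,M,ND,1.4,54,54,2.4,1.6
13,78,M,0.75,4.0,61,76,3.0,2.0
14,55,F,ND,0.43,17,19,3.1,2.6
15,32,F,ND,Trace,62,44,8.5,7.9
16,32,F,ND,ND,26,25,3.8,3.7
17,80,M,0.48,2.7,91,93,2.5,1.5
18,82,M,1.0,3.1,89,91,4.1,2.3
19,78,F,1.1,2.4,76,82,2.7,1.8
20,70,M,ND,ND,5.4,6.1,0.98,1.0
21,81,F,ND,0.48,31,37,2.0,
22,79,F,ND,Trace,32,32,1.6,1.3
23,77,M,0.82,1.8,54,54,3.0,2.7
24,54,M,ND,ND,90,100,0.94,0.92
25,58,M,1.8,2.9,16,9.7,3.8,4.3
26,60,M,ND,ND,8.7,6.1,2.6,2.5
27,49,M,Trace,Trace,13,13,6.4,6.5
28,39,M,Trace,Trace,77,77,7.9,7.6
29,31,F,ND,ND,85,84,2.2,1.5
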