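# fireCN reference-groups v1
# Reference exposure estimates and exposure-group assignment accompanying
# the packaged cohort (doubly-quantified cases only). ref_conc_ppm /
# ref_time_min are the published reference reconstruction, reported here
# as data; the package recomputes its own estimates from its shipped
# parameter set.
case_id,cn_right,cn_left,scn_right,scn_left,ref_conc_ppm,ref_time_min,group
5,0.58,2.7,2.6,1.5,14100,0.05,Ca_high_T_short
7,1.2,1.7,3.2,2.8,1260,0.40,Ca_high_T_short
9,1.1,11,4.5,2.4,16212,0.20,Ca_high_T_short
13,0.75,4.0,3.0,2.0,11040,0.10,Ca_high_T_short
17,0.48,2.7,2.5,1.5,14280,0.05,Ca_high_T_short
18,1.0,3.1,4.1,2.3,16632,0.05,Ca_high_T_short
19,1.1,2.4,2.7,1.8,6624,0.10,Ca_high_T_short
23,0.82,1.8,3.0,2.7,5004,0.10,Ca_high_T_short
1,2.0,3.7,2.2,2.1,1032,8.35,Ca_low_T_long
2,1.7,2.9,1.7,1.4,696,6.60,Ca_low_T_long
4,0.64,0.67,2.0,2.1,84,2.40,Ca_low_T_long
10,2.3,4.0,2.8,2.3,996,13.65,Ca_low_T_long
25,1.8,2.9,3.8,4.3,648,9.10,Ca_low_T_long
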