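nce,qtc_ec5,px_apd90_dir,px_emw_dir,px_insilico_label,px_tpkpd_ec5,px_adjusted_label,hts_apd90_dir,hts_emw_dir,hts_insilico_label,hts_tpkpd_ec5,hts_adjusted_label
1,0.07,up,down,TP,0.03,TP,up,down,TP,0.08,TP
2,1.2,up,down,TP,2.4,TP,NA,NA,NA,NA,NA
3,1.8,up,down,TP,1.9,TP,up,down,TP,4.8,TP
4,1.6,up,down,TP,1.5,TP,NA,NA,NA,NA,NA
5,0.02,up,down-up,TP,0.02,TP,up,down,TP,0.21,FN
6,>3,up,up,TN,2.9,TN,NA,NA,NA,NA,NA
7,12,up,down,TP,15,TP,NA,NA,NA,NA,NA
8,>0.7,up,up,TN,1.3,TN,up,up,TN,0.5,TN
9,>2,up,up,TN,1.9,TN,up,up,TN,5.7,TN
10,1.6,up,down,TP,6.01,TP,NA,NA,NA,NA,NA
11,>5,up,up,TN,3.1,TN,up,up,TN,0.3,TN
12,>8.7,up,down,FP,9.2,TN,up,up,TN,468,TN
13,1,up,down,TP,0.4,TP,NA,NA,TP,0.1,TP
14,>5.4,up,up,TN,10.9,TN,up,up,TN,2.5,TN
15,>20,up,down,FP,28,TN,up,down,FP,32,TN
16,10,up,down,TP,19.9,TP,NA,NA,NA,NA,NA
17,>5,up,up,TN,3.4,TN,up,up,TN,3,TN
18,>0.385,up,up,TN,17,TN,up,up,TN,4.3,TN
19,>0.05,up,up,TN,2,TN,up,down,FP,0.08,TN
20,>7.7,up,down,FP,6.1,FP,up,down,FP,1.1,FP
21,>0.1,up,down,FP,5.2,TN,NA,NA,NA,NA,NA
22,>0.89,up,up,TN,2.2,TN,up,up,TN,6.9,TN
23,5,up,down,TP,9.1,TP,NA,NA,NA,NA,NA
24,7.2,up,down-up,TP,1,TP,up,up,FN,4.9,FN
25,1.2,up,down,TP,5.1,TP,NA,NA,NA,NA,NA
26,1,up,down,TP,1.6,TP,NA,NA,NA,NA,NA
27,>4.5,up,down,FP,4.7,TN,up,down,FP,6.4,TN
28,>4.6,up,up,TN,1.4,TN,up,up,TN,0.5,TN
29,>0.14,down,up,TN,12,TN,down,down,TN,1.2,TN
30,4,up,down,TP,14.1,TP,up,down,TP,5.6,TP
31,>2,up,down,FP,3.6,TN,up,down,FP,5.7,TN
32,6,up,down,TP,9.6,TP,NA,NA,NA,NA,NA
33,>0.1,up,up,TN,4.2,TN,up,down,FP,0.9,TN
34,>16,up,up,TN,18,TN,up,up,TN,3.1,TN
35,>45.8,up,up,TN,5.6,TN,up,up,TN,0.5,TN
36,3.5,up,down,TP,3.6,TP,NA,NA,NA,NA,NA
37,>2.5,up,down,FP,3,TN,up,down,FP,8.5,TN
38,>60,up,up,TN,1.2,TN,up,up,TN,0.9,TN
39,0.9,up,down,TP,1.2,TP,up,down,TP,2,TP
40,1.4,up,down,TP,2,TP,up,up,FN,0.9,FN
41,>4.4,up,down,FP,5.2,TN,NA,NA,NA,NA,NA
42,>0.27,up,up,TN,1.9,TN,up,up,TN,1.9,TN
43,>5.5,up,up,TN,2.1,TN,up,up,TN,0.6,TN
44,>1.98,up,up,TN,2.4,TN,up,up,TN,2,TN
45,44,up,down,TP,29,TP,up,down,TP,5,TP
46,0.988,up,down,TP,1,TP,up,down,TP,2,TP
47,>0.2,up,up,TN,1.3,TN,up,up,TN,3,TN
48,>4.7,up,up,TN,2.7,TN,up,up,TN,1,TN
49,>0.3,up,up,TN,4.2,TN,down,up,TN,147,TN
50,>31,up,up,TN,134,TN,NA,NA,NA,NA,NA
51,0.3,up,down,TP,0.5,TP,up,down,TP,0.07,TP
52,2.8,up,down,TP,5.2,TP,up,down,TP,12.5,TP
53,0.4,up,down,TP,1,TP,NA,NA,NA,NA,NA
54,>0.4,up,up,TN,0.6,TN,NA,NA,NA,NA,NA
55,>1,up,up,TN,0.4,TN,up,up,TN,0.16,TN
56,1.8,up,down,TP,0.5,TP,up,up,FN,0.12,FN
57,2,up,down,TP,1,TP,up,down,TP,4.1,TP
58,0.23,up,down,TP,0.2,TP,up,down,TP,0.12,TP
59,>3.3,up,down,FP,0.2,FP,NA,NA,NA,NA,NA
60,19.9,up,down,TP,10,TP,NA,NA,NA,NA,NA
61,0.1,up,down,TP,0.5,TP,up,up,FN,0.04,FN
62,>0.2,up,up,TN,0.4,TN,up,up,TN,0.12,TN
63,>0.4,down-up,up,TN,0.4,TN,up,up,TN,0.12,TN
64,>0.07,up,down,FP,0.5,TN,down,up,TN,18.9,TN
65,1,up,down,TP,0.2,TP,up,down,TP,0.1,TP
66,>3.4,up,up,TN,0.5,TN,up,up,TN,0.3,TN
67,0.3,up,down,TP,0.4,TP,NA,NA,NA,NA,NA
68,3,up,down,TP,0.7,TP,up,up,FN,3.1,FN
69,0.5,up,down,TP,0.6,TP,down,up,FN,37,FN
70,1.2,up,down,TP,1,TP,up,down,TP,3.8,TP
71,>2.3,up,up,TN,4.2,TN,NA,NA,NA,NA,NA
72,>5.4,up,down,FP,34,TN,NA,NA,NA,NA,NA
73,>0.8,up,up,TN,1,TN,NA,NA,NA,NA,NA
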