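nce,qtc_ec5,px_herg_ic20,px_label,hts_mk499_ic20,hts_label
1,0.07,0.004,TP,0.003,TP
2,1.2,0.2,TP,NA,NA
3,1.8,12,FN,9.2,FN
4,1.6,0.4,TP,NA,NA
5,0.02,0.0028,TP,0.3,FN
6,>3,1.04,FP,NA,NA
7,15,15.2,TP,NA,NA
8,>0.7,4.8,TN,0.8,TN
9,>2,12,TN,1.9,FP
10,1.6,8.1,FN,NA,NA
11,>5,2.6,FP,8.2,TN
12,>8.7,7.5,FP,>30,TN
13,1,0.2,TP,0.1,TP
14,>5.4,12,TN,3.5,FP
15,>20,21,TN,19.2,FP
16,10,8.7,TP,NA,NA
17,>5.5,5,FP,12.4,TN
18,>0.385,8.4,TN,12.6,TN
19,>0.05,16,TN,0.82,FP
20,>7.7,9.2,TN,18.5,TN
21,>0.1,4.3,TN,NA,NA
22,>0.89,10.1,TN,15.4,TN
23,5,17,FN,ND,NA
24,7.2,1.5,TP,15.2,TP
25,1.2,6.5,FN,ND,NA
26,1,0.2,TP,NA,NA
27,>4.5,21,TN,14.2,TN
28,>4.6,4.2,FP,11.1,TN
29,>0.14,12,TN,16.2,TN
30,4,3.5,TP,8.2,TP
31,>2,8,TN,12.5,TN
32,6,7.5,TP,NA,NA
33,>0.1,16,TN,1.6,TN
34,>16,7.2,FP,14.8,FP
35,>45.8,8.4,FP,12.48,FP
36,3.5,1.5,TP,NA,NA
37,>2.5,10.8,TN,14.2,TN
38,>60,3.5,FP,2.4,FP
39,0.9,3.5,TP,4.1,TP
40,1.4,7.6,FN,18.5,FN
41,>4.4,2.5,FP,NA,NA
42,>0.27,8.3,TN,3.5,TN
43,>5.5,12,TN,18.2,TN
44,>1.98,16,TN,6.5,TN
45,44,19.4,TP,10.5,TP
46,0.988,2.5,TP,3.8,TP
47,>0.2,3.6,TN,6.4,TN
48,>4.7,20.6,TN,16.2,TN
49,>0.3,15.4,TN,6.8,TN
50,>31,33.3,TN,NA,NA
51,0.3,0.2,TP,1.1,TP
52,2.8,5.4,TP,2.1,TP
53,0.42,2,TP,NA,NA
54,>0.4,0.8,TN,NA,NA
55,>1,0.56,FP,0.68,FP
56,1.8,0.2,TP,6.44,TP
57,2,1.4,TP,10.1,FN
58,0.23,0.056,TP,0.168,TP
59,>3.3,0.132,FP,NA,NA
60,19.9,8.2,TP,NA,NA
61,0.1,0.34,TP,0.8,FN
62,>0.2,3.4,TN,1.1,TN
63,>0.4,5.2,TN,1.3,TN
64,>0.07,0.8,TN,ND,TN
65,1,0.33,TP,1.1,TP
66,>3.4,0.56,FP,0.9,FP
67,0.3,0.05,TP,NA,NA
68,3,1.1,TP,8.2,TP
69,0.5,0.6,TP,NA,NA
70,1.2,1.7,TP,6.5,FN
71,>2.3,6.2,TN,NA,NA
72,>5.4,28.4,TN,NA,NA
73,>0.8,1.4,TN,NA,NA
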