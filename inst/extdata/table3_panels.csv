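nce,px_herg_ic50,px_hnav15_ic50,px_iks_ic50,hts_hcav12_ic50,hts_mk499_ic50,hts_hnav15_ic50
1,0.01,8.3,ND,3.25,0.014,3
2,0.95,9.4,270,ND,NA,NA
3,26.5,ND,ND,ND,26,NA
4,1,0.6,100,ND,NA,NA
5,0.007,6.7,ND,3,1.1,5.3
6,2.6,11,5.9,0.1,NA,NA
7,42,ND,ND,ND,NA,NA
8,12,68,5.7,7.4,3.1,12.4
9,36,15,79,16.2,9.9,0.5
10,18,14,ND,ND,NA,NA
11,8.2,48,100,12.6,24.7,ND
12,27,68,150,ND,NA,NA
13,0.86,100,ND,5.1,0.3,3.5
14,27,75,ND,13.3,10.8,4.7
15,55,ND,ND,ND,53,ND
16,25,ND,ND,ND,NA,NA
17,15,43,21,16.9,32.6,39
18,21,94,ND,13.4,34.3,12.9
19,40,4,56,27,2.2,ND
20,27,ND,ND,79,49,ND
21,11,19,13,ND,NA,NA
22,26,43,150,35,41.6,15.2
23,31,45,ND,ND,NA,NA
24,6.4,100,ND,11,47,14
25,8.1,36,ND,ND,NA,NA
26,0.5,81,144,ND,NA,NA
27,50,ND,ND,ND,38,ND
28,14,ND,ND,21.4,34.9,ND
29,40,50,ND,2.8,46,136
30,11,ND,ND,ND,32.3,ND
31,22,ND,ND,ND,33,ND
32,23,36,ND,ND,NA,NA
33,48,4.1,38,19,5.7,29.4
34,22,55,ND,7,41.9,23.4
35,26,ND,ND,21.5,31.2,ND
36,4.5,16,63,ND,NA,NA
37,29,ND,ND,115,39,29
38,12,42,ND,6.9,6.4,10.9
39,10,94,ND,27.9,10.4,19.2
40,21,19,ND,43,56.5,ND
41,8.5,38,ND,ND,NA,NA
42,26,41,51,6.4,11.1,12.7
43,35,ND,83,18.6,50,ND
44,47,21,29,13.8,18.4,28.8
45,58,ND,ND,ND,28,ND
46,5.3,ND,ND,107,10.9,94
47,12,36,115,18.4,19.8,15.1
48,56,68,48,28.7,47.2,88
49,44,60,ND,9.1,ND,83
50,82,53,ND,ND,NA,NA
51,0.95,45,ND,17.5,3.6,ND
52,19,150,83,ND,6.3,31.8
53,5.4,ND,ND,300,NA,NA
54,2.5,60.9,15,3.12,NA,NA
55,2.1,23,300,0.785,1.7,5.6
56,1,70,106,3,16.1,ND
57,4.8,0.94,300,ND,26.7,ND
58,0.14,63,83,12.3,0.4,22.8
59,0.33,7.5,95,10,NA,NA
60,25,ND,ND,26,NA,NA
61,1.8,17,14,4.9,3,ND
62,4.3,15,3.7,0.47,3.8,31
63,9.1,90,300,0.195,3.8,7.5
64,1.5,300,300,4.1,ND,ND
65,1.1,12,60,1.3,3.6,ND
66,2.2,300,300,1.75,3.3,20.3
67,0.14,ND,ND,ND,NA,NA
68,4,ND,ND,19.04,22.9,19.5
69,2,ND,ND,20.4,ND,ND
70,5,53.3,300,ND,19.5,ND
71,11,13.5,ND,3.087,NA,NA
72,83,35,ND,ND,NA,NA
73,3.3,6.9,13.6,1.251,NA,NA
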