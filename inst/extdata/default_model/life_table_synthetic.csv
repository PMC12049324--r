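age,qx
0,0.00030795257
1,0.00030883798
2,0.00030982142
3,0.00031091373
4,0.00031212697
5,0.00031347453
6,0.00031497127
7,0.00031663372
8,0.00031848021
9,0.00032053113
10,0.00032280909
11,0.00032533925
12,0.00032814952
13,0.0003312709
14,0.00033473784
15,0.0003385886
16,0.00034286566
17,0.00034761621
18,0.00035289267
19,0.00035875326
20,0.00036526263
21,0.00037249262
22,0.00038052298
23,0.00038944231
24,0.00039934901
25,0.00041035238
26,0.00042257379
27,0.00043614806
28,0.00045122494
29,0.00046797072
30,0.0004865701
31,0.00050722823
32,0.00053017294
33,0.00055565724
34,0.00058396217
35,0.00061539982
36,0.00065031679
37,0.000689098
38,0.00073217095
39,0.00078001035
40,0.00083314339
41,0.00089215552
42,0.00095769682
43,0.0010304892
44,0.0011113343
45,0.0012011221
46,0.0013008409
47,0.0014115879
48,0.0015345814
49,0.0016711739
50,0.0018228667
51,0.0019913265
52,0.0021784032
53,0.0023861502
54,0.0026168463
55,0.0028730204
56,0.0031574786
57,0.0034733341
58,0.003824041
59,0.0042134301
60,0.0046457502
61,0.0051257129
62,0.0056585411
63,0.0062500247
64,0.0069065793
65,0.007635313
66,0.0084440985
67,0.0093416524
68,0.010337623
69,0.011442684
70,0.012668641
71,0.014028542
72,0.015536803
73,0.01720934
74,0.019063715
75,0.021119287
76,0.023397384
77,0.025921476
78,0.028717366
79,0.031813385
80,0.035240599
81,0.039033023
82,0.043227836
83,0.047865599
84,0.052990465
85,0.058650379
86,0.064897263
87,0.071787162
88,0.079380355
89,0.087741406
90,0.096939133
91,0.10704648
92,0.11814027
93,0.13030078
94,0.14361112
95,0.15815641
96,0.17402261
97,0.1912951
98,0.21005677
99,0.23038578
100,0.25235276
101,0.27601754
102,0.30142526
103,0.32860205
104,0.35755007
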