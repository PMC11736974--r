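"age","qx"
0,0.000304592
1,0.000314443
2,0.000325222
3,0.000337015
4,0.00034992
5,0.000364039
6,0.000379488
7,0.000396391
8,0.000414886
9,0.000435122
10,0.000457264
11,0.00048149
12,0.000507997
13,0.000536999
14,0.000568732
15,0.000603452
16,0.00064144
17,0.000683004
18,0.00072848
19,0.000778237
20,0.000832677
21,0.00089224
22,0.000957408
23,0.00102871
24,0.00110672
25,0.00119207
26,0.00128545
27,0.00138761
28,0.00149938
29,0.00162166
30,0.00175544
31,0.0019018
32,0.00206192
33,0.00223709
34,0.00242872
35,0.00263835
36,0.00286768
37,0.00311854
38,0.00339296
39,0.00369313
40,0.00402146
41,0.00438059
42,0.0047734
43,0.00520302
44,0.00567288
45,0.00618674
46,0.00674869
47,0.0073632
48,0.00803514
49,0.00876984
50,0.0095731
51,0.0104513
52,0.0114112
53,0.0124606
54,0.0136074
55,0.0148608
56,0.0162303
57,0.0177266
58,0.0193613
59,0.0211467
60,0.0230966
61,0.0252257
62,0.02755
63,0.0300868
64,0.0328549
65,0.0358746
66,0.039168
67,0.0427586
68,0.0466719
69,0.0509355
70,0.0555787
71,0.0606332
72,0.0661328
73,0.0721133
74,0.0786132
75,0.0856731
76,0.0933358
77,0.101647
78,0.110653
79,0.120404
80,0.130951
81,0.142346
82,0.154643
83,0.167897
84,0.18216
85,0.197487
86,0.213929
87,0.231533
88,0.250343
89,0.270398
90,0.291728
91,0.314352
92,0.33828
93,0.363506
94,0.390007
95,0.417741
96,0.446644
97,0.476628
98,0.507578
99,0.539349
100,0.571768
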