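"z_um","ch_647","ch_bf","ch_488"
0,0.00397,0,0.0723
0.5,0.02308,0.0384,0.05067
1,0.1514,0,0.03987
1.5,0.11983,0,0
2,0.11547,0.03371,0
2.5,0.17687,0,0.04685
3,0.2747,0,0.01949
3.5,0.22826,0.04367,0
4,0.23688,0.0246,0
4.5,0.27345,0.01961,0.01688
5,0.37606,0,0
5.5,0.57231,0,0.05901
6,0.55663,0.00685,0.04528
6.5,0.59797,0,0.00611
7,0.74001,0.01752,0
7.5,0.75528,0,0.02367
8,0.94235,0.0095,0.0612
8.5,0.98721,0,0
9,0.91167,0,0.11208
9.5,0.9342,0.09782,0
10,1.00167,0,0
10.5,1.04563,0,0.01823
11,0.97402,0,0
11.5,0.97654,0,0
12,0.92309,0.07221,0
12.5,0.86774,0,0
13,0.78566,0.01021,0
13.5,0.60187,0,0.03667
14,0.61161,0.0091,0
14.5,0.55799,0,0
15,0.42103,0.10787,0
15.5,0.41202,0,0.02748
16,0.25357,0.08206,0
16.5,0.27579,0.00958,0
17,0.24292,0,0
17.5,0.12737,0,0
18,0.1908,0,0.01225
18.5,0.08813,0,0.04481
19,0.01637,0,0
19.5,0.0624,0.02794,0.04853
20,0,0.02586,0.01893
20.5,0,0,0.04051
21,0.01812,0.0255,0
21.5,0,0,0
22,0,0,0.11882
22.5,0,0.02086,0
23,0.00261,0,0
23.5,0.05052,0,0.06652
24,0.02092,0.10833,0.10871
24.5,0,0.04389,0.04603
25,0.01576,0.01482,0.06671
25.5,0,0.05191,0
26,0.06514,0,0.00424
26.5,0,0,0
27,0.02053,0,0
27.5,0.02626,0.01538,0
28,0.09525,0.05575,0
28.5,0,0,0.02968
29,0,0,0.08035
29.5,0.07372,0.11627,0.06864
30,0,0.05614,0.0739
30.5,0,0,0.0578
31,0.0851,0.05558,0
31.5,0.01452,0.0358,0
32,0,0.11327,0
32.5,0.00241,0.05203,0
33,0,0,0
33.5,0,0.0595,0
34,0,0.07258,0.00588
34.5,0.01159,0,0
35,0.01779,0,0.04604
35.5,0.00321,0,0
36,0,0,0.04936
36.5,0.10964,0.04224,0.00202
37,0,0,0.05768
37.5,0,0,0.01095
38,0.04226,0,0
38.5,0.11141,0,0.05742
39,0.06149,0,0
39.5,0,0.06906,0.01916
40,0,0.01382,0
40.5,0.03053,0,0
41,0.01827,0,0
41.5,0,0,0
42,0.04212,0.03319,0.03664
42.5,0,0,0.04242
43,0.02333,0,0.03915
43.5,0,0,0
44,0.06669,0.07041,0.01549
44.5,0.00936,0.02597,0.01043
45,0.02313,0.1381,0.03563
45.5,5e-05,0,0
46,0,0,0.02153
46.5,0.03168,0.06706,0.06047
47,0.01817,0.08326,0
47.5,0,0,0
48,0,0.01351,0.0154
48.5,0.01174,0,0.02371
49,0.03382,0,0
49.5,0,0,0
50,0,0.03416,0.04803
50.5,0,0.00558,0.00012
51,0,0,0
51.5,0.06908,0.05651,0.1147
52,0,0,0
52.5,0,0.01992,0
53,0.04817,0.0673,0
53.5,0,0.02165,0
54,0,0.00715,0.06018
54.5,0.03069,0.0197,0.10677
55,0.00974,0,0.07633
55.5,0,0,0
56,0,0,0.03191
56.5,0.08843,0.07538,0
57,0,0.11354,0
57.5,0,0.0357,0.00014
58,0.0181,0.1258,0.09509
58.5,0,0.1383,0
59,0.03419,0.16289,0
59.5,0,0.2064,0.00421
60,0.05685,0.20771,0
60.5,0,0.25157,0.06685
61,0.06549,0.3293,2e-04
61.5,0.02629,0.38271,0
62,0,0.4545,0
62.5,0.05592,0.60172,0.02838
63,0,0.65733,0.00887
63.5,0.033,0.6856,0.04656
64,0.0169,0.72672,0.00907
64.5,0.06611,0.72904,0.06375
65,0.07137,0.8915,0
65.5,0.08758,0.93095,0
66,0,0.88837,0
66.5,0,0.91209,0
67,0,1.01266,0.06334
67.5,0.03727,1.04082,0
68,0.05608,0.97045,0.06652
68.5,0.02115,0.89986,0
69,0.0307,0.82971,0.01379
69.5,0,0.77822,0
70,0.04035,0.87001,0.04864
70.5,0,0.72326,0.10659
71,0.01943,0.51593,0.14244
71.5,0,0.4858,0.05066
72,0.04046,0.47152,0.05366
72.5,0,0.37311,0.22922
73,0,0.31059,0.19082
73.5,0,0.32993,0.1304
74,0.05316,0.16863,0.36741
74.5,0,0.17984,0.41933
75,0,0.0458,0.42244
75.5,0.02133,0.08319,0.51224
76,0,0.0966,0.60308
76.5,0.00147,0.02594,0.66864
77,0.00304,0.04629,0.63176
77.5,0.00996,0.04937,0.82917
78,0.06605,0.0432,0.89897
78.5,0,0.05017,0.92664
79,0,0.02029,0.91153
79.5,0,0.03132,0.97027
80,0.0416,0,1.0369
80.5,0.06433,0,1.00021
81,0,0.10726,0.9662
81.5,0,0.03382,0.94269
82,0.02336,0,0.90273
82.5,0,0.02693,0.8856
83,0,0.0154,0.82905
83.5,0.08821,0,0.76302
84,0.03763,0,0.57894
84.5,0,0,0.54866
85,0.07925,0.02352,0.50374
85.5,0,0.00418,0.44223
86,0,0,0.38774
86.5,0,0,0.30484
87,0,0,0.30885
87.5,0.06274,0.04272,0.1975
88,0,0.02125,0.09477
88.5,0,0,0.21896
89,0,0,0.06023
89.5,0.09795,0,0.10974
90,0.00888,0.03318,0.08586
90.5,0.03781,0.04763,0.07874
91,0,0,0.02155
91.5,0.02106,0,0.01493
92,0.02747,0,0.04413
92.5,0.08558,0,0
93,0.05407,0.01879,0.05016
93.5,0,0,0
94,0.00556,0.03714,0
94.5,0.01277,0,0
95,0,0.03847,0
95.5,0,0,0.03738
96,0.09369,0,0.01435
96.5,0,0.0739,0
97,0,0,0.04287
97.5,0.00398,0.04182,0
98,0.00922,0.13321,0.02046
98.5,0,0.05822,0.05607
99,0,0,0.15005
99.5,0,0.03164,0.03959
100,0.07559,0,0.01751
100.5,0,0,0
101,0,0,0.06568
101.5,0.00344,0,0.00577
102,0,0,0
102.5,0.0231,0.01923,0
103,0,0,0
103.5,0,0.06673,0.03713
104,0.01797,0.00551,0
104.5,0.07309,0,0
105,0,0,0
105.5,0,0,0
106,0.00716,0.00082,0
106.5,0.05702,0.09854,0
107,0.12942,0.0099,0.02224
107.5,0,0,0
108,0.12018,0.06234,0.02239
108.5,0,0.05459,0.05998
109,0,0.00252,0
109.5,0.02963,0.05841,0
110,0.06789,0,0
110.5,0.00138,0,0.00807
111,0,0.05515,0
111.5,0.04992,0,0.00321
112,0,0.06425,0.00711
112.5,0.09756,0.02485,0.05981
113,0,0,0
113.5,0,0.04239,0
114,0,0.05743,0
114.5,0.08973,0.04829,0.04915
115,0.01704,0,0
115.5,0.03203,0,0.03311
116,0.00746,0.00559,0
116.5,0,0.00796,0.09089
117,0.03771,0.01134,0.00565
117.5,0,0,0
118,0.02314,0.01529,0
118.5,0.02413,0.0251,0
119,0.01043,0.06706,0.06116
119.5,0.02088,0.00552,0
120,0,0,0
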