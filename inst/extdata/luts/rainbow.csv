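index,R,G,B
0,0.500000,0.000000,1.000000
1,0.492157,0.012320,0.999981
2,0.484314,0.024637,0.999924
3,0.476471,0.036951,0.999829
4,0.468627,0.049260,0.999696
5,0.460784,0.061561,0.999526
6,0.452941,0.073853,0.999317
7,0.445098,0.086133,0.999070
8,0.437255,0.098400,0.998786
9,0.429412,0.110653,0.998464
10,0.421569,0.122888,0.998103
11,0.413725,0.135105,0.997705
12,0.405882,0.147302,0.997269
13,0.398039,0.159476,0.996795
14,0.390196,0.171626,0.996284
15,0.382353,0.183750,0.995734
16,0.374510,0.195845,0.995147
17,0.366667,0.207912,0.994522
18,0.358824,0.219946,0.993859
19,0.350980,0.231948,0.993159
20,0.343137,0.243914,0.992421
21,0.335294,0.255843,0.991645
22,0.327451,0.267733,0.990831
23,0.319608,0.279583,0.989980
24,0.311765,0.291390,0.989092
25,0.303922,0.303153,0.988165
26,0.296078,0.314870,0.987202
27,0.288235,0.326539,0.986201
28,0.280392,0.338158,0.985162
29,0.272549,0.349727,0.984086
30,0.264706,0.361242,0.982973
31,0.256863,0.372702,0.981823
32,0.249020,0.384106,0.980635
33,0.241176,0.395451,0.979410
34,0.233333,0.406737,0.978148
35,0.225490,0.417960,0.976848
36,0.217647,0.429121,0.975512
37,0.209804,0.440216,0.974139
38,0.201961,0.451244,0.972728
39,0.194118,0.462204,0.971281
40,0.186275,0.473094,0.969797
41,0.178431,0.483911,0.968276
42,0.170588,0.494656,0.966718
43,0.162745,0.505325,0.965124
44,0.154902,0.515918,0.963493
45,0.147059,0.526432,0.961826
46,0.139216,0.536867,0.960122
47,0.131373,0.547220,0.958381
48,0.123529,0.557489,0.956604
49,0.115686,0.567675,0.954791
50,0.107843,0.577774,0.952942
51,0.100000,0.587785,0.951057
52,0.092157,0.597707,0.949135
53,0.084314,0.607539,0.947177
54,0.076471,0.617278,0.945184
55,0.068627,0.626924,0.943154
56,0.060784,0.636474,0.941089
57,0.052941,0.645928,0.938988
58,0.045098,0.655284,0.936852
59,0.037255,0.664540,0.934680
60,0.029412,0.673696,0.932472
61,0.021569,0.682749,0.930229
62,0.013725,0.691698,0.927951
63,0.005882,0.700543,0.925638
64,0.001961,0.709281,0.923289
65,0.009804,0.717912,0.920906
66,0.017647,0.726434,0.918487
67,0.025490,0.734845,0.916034
68,0.033333,0.743145,0.913545
69,0.041176,0.751332,0.911023
70,0.049020,0.759405,0.908465
71,0.056863,0.767363,0.905873
72,0.064706,0.775204,0.903247
73,0.072549,0.782928,0.900587
74,0.080392,0.790532,0.897892
75,0.088235,0.798017,0.895163
76,0.096078,0.805381,0.892401
77,0.103922,0.812622,0.889604
78,0.111765,0.819740,0.886774
79,0.119608,0.826734,0.883910
80,0.127451,0.833602,0.881012
81,0.135294,0.840344,0.878081
82,0.143137,0.846958,0.875117
83,0.150980,0.853444,0.872120
84,0.158824,0.859800,0.869089
85,0.166667,0.866025,0.866025
86,0.174510,0.872120,0.862929
87,0.182353,0.878081,0.859800
88,0.190196,0.883910,0.856638
89,0.198039,0.889604,0.853444
90,0.205882,0.895163,0.850217
91,0.213725,0.900587,0.846958
92,0.221569,0.905873,0.843667
93,0.229412,0.911023,0.840344
94,0.237255,0.916034,0.836989
95,0.245098,0.920906,0.833602
96,0.252941,0.925638,0.830184
97,0.260784,0.930229,0.826734
98,0.268627,0.934680,0.823253
99,0.276471,0.938988,0.819740
100,0.284314,0.943154,0.816197
101,0.292157,0.947177,0.812622
102,0.300000,0.951057,0.809017
103,0.307843,0.954791,0.805381
104,0.315686,0.958381,0.801714
105,0.323529,0.961826,0.798017
106,0.331373,0.965124,0.794290
107,0.339216,0.968276,0.790532
108,0.347059,0.971281,0.786745
109,0.354902,0.974139,0.782928
110,0.362745,0.976848,0.779081
111,0.370588,0.979410,0.775204
112,0.378431,0.981823,0.771298
113,0.386275,0.984086,0.767363
114,0.394118,0.986201,0.763398
115,0.401961,0.988165,0.759405
116,0.409804,0.989980,0.755383
117,0.417647,0.991645,0.751332
118,0.425490,0.993159,0.747253
119,0.433333,0.994522,0.743145
120,0.441176,0.995734,0.739009
121,0.449020,0.996795,0.734845
122,0.456863,0.997705,0.730653
123,0.464706,0.998464,0.726434
124,0.472549,0.999070,0.722186
125,0.480392,0.999526,0.717912
126,0.488235,0.999829,0.713610
127,0.496078,0.999981,0.709281
128,0.503922,0.999981,0.704926
129,0.511765,0.999829,0.700543
130,0.519608,0.999526,0.696134
131,0.527451,0.999070,0.691698
132,0.535294,0.998464,0.687237
133,0.543137,0.997705,0.682749
134,0.550980,0.996795,0.678235
135,0.558824,0.995734,0.673696
136,0.566667,0.994522,0.669131
137,0.574510,0.993159,0.664540
138,0.582353,0.991645,0.659925
139,0.590196,0.989980,0.655284
140,0.598039,0.988165,0.650618
141,0.605882,0.986201,0.645928
142,0.613725,0.984086,0.641213
143,0.621569,0.981823,0.636474
144,0.629412,0.979410,0.631711
145,0.637255,0.976848,0.626924
146,0.645098,0.974139,0.622113
147,0.652941,0.971281,0.617278
148,0.660784,0.968276,0.612420
149,0.668627,0.965124,0.607539
150,0.676471,0.961826,0.602635
151,0.684314,0.958381,0.597707
152,0.692157,0.954791,0.592758
153,0.700000,0.951057,0.587785
154,0.707843,0.947177,0.582791
155,0.715686,0.943154,0.577774
156,0.723529,0.938988,0.572735
157,0.731373,0.934680,0.567675
158,0.739216,0.930229,0.562593
159,0.747059,0.925638,0.557489
160,0.754902,0.920906,0.552365
161,0.762745,0.916034,0.547220
162,0.770588,0.911023,0.542053
163,0.778431,0.905873,0.536867
164,0.786275,0.900587,0.531659
165,0.794118,0.895163,0.526432
166,0.801961,0.889604,0.521185
167,0.809804,0.883910,0.515918
168,0.817647,0.878081,0.510631
169,0.825490,0.872120,0.505325
170,0.833333,0.866025,0.500000
171,0.841176,0.859800,0.494656
172,0.849020,0.853444,0.489293
173,0.856863,0.846958,0.483911
174,0.864706,0.840344,0.478512
175,0.872549,0.833602,0.473094
176,0.880392,0.826734,0.467658
177,0.888235,0.819740,0.462204
178,0.896078,0.812622,0.456733
179,0.903922,0.805381,0.451244
180,0.911765,0.798017,0.445738
181,0.919608,0.790532,0.440216
182,0.927451,0.782928,0.434676
183,0.935294,0.775204,0.429121
184,0.943137,0.767363,0.423549
185,0.950980,0.759405,0.417960
186,0.958824,0.751332,0.412356
187,0.966667,0.743145,0.406737
188,0.974510,0.734845,0.401102
189,0.982353,0.726434,0.395451
190,0.990196,0.717912,0.389786
191,0.998039,0.709281,0.384106
192,1.000000,0.700543,0.378411
193,1.000000,0.691698,0.372702
194,1.000000,0.682749,0.366979
195,1.000000,0.673696,0.361242
196,1.000000,0.664540,0.355491
197,1.000000,0.655284,0.349727
198,1.000000,0.645928,0.343949
199,1.000000,0.636474,0.338158
200,1.000000,0.626924,0.332355
201,1.000000,0.617278,0.326539
202,1.000000,0.607539,0.320710
203,1.000000,0.597707,0.314870
204,1.000000,0.587785,0.309017
205,1.000000,0.577774,0.303153
206,1.000000,0.567675,0.297277
207,1.000000,0.557489,0.291390
208,1.000000,0.547220,0.285492
209,1.000000,0.536867,0.279583
210,1.000000,0.526432,0.273663
211,1.000000,0.515918,0.267733
212,1.000000,0.505325,0.261793
213,1.000000,0.494656,0.255843
214,1.000000,0.483911,0.249883
215,1.000000,0.473094,0.243914
216,1.000000,0.462204,0.237935
217,1.000000,0.451244,0.231948
218,1.000000,0.440216,0.225951
219,1.000000,0.429121,0.219946
220,1.000000,0.417960,0.213933
221,1.000000,0.406737,0.207912
222,1.000000,0.395451,0.201882
223,1.000000,0.384106,0.195845
224,1.000000,0.372702,0.189801
225,1.000000,0.361242,0.183750
226,1.000000,0.349727,0.177691
227,1.000000,0.338158,0.171626
228,1.000000,0.326539,0.165554
229,1.000000,0.314870,0.159476
230,1.000000,0.303153,0.153392
231,1.000000,0.291390,0.147302
232,1.000000,0.279583,0.141206
233,1.000000,0.267733,0.135105
234,1.000000,0.255843,0.128999
235,1.000000,0.243914,0.122888
236,1.000000,0.231948,0.116773
237,1.000000,0.219946,0.110653
238,1.000000,0.207912,0.104528
239,1.000000,0.195845,0.098400
240,1.000000,0.183750,0.092268
241,1.000000,0.171626,0.086133
242,1.000000,0.159476,0.079994
243,1.000000,0.147302,0.073853
244,1.000000,0.135105,0.067708
245,1.000000,0.122888,0.061561
246,1.000000,0.110653,0.055411
247,1.000000,0.098400,0.049260
248,1.000000,0.086133,0.043107
249,1.000000,0.073853,0.036951
250,1.000000,0.061561,0.030795
251,1.000000,0.049260,0.024637
252,1.000000,0.036951,0.018479
253,1.000000,0.024637,0.012320
254,1.000000,0.012320,0.006160
255,1.000000,0.000000,0.000000
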