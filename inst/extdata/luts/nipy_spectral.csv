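index,R,G,B
0,0.000000,0.000000,0.000000
1,0.036604,0.000000,0.041827
2,0.073208,0.000000,0.083655
3,0.109812,0.000000,0.125482
4,0.146416,0.000000,0.167310
5,0.183020,0.000000,0.209137
6,0.219624,0.000000,0.250965
7,0.256227,0.000000,0.292792
8,0.292831,0.000000,0.334620
9,0.329435,0.000000,0.376447
10,0.366039,0.000000,0.418275
11,0.402643,0.000000,0.460102
12,0.439247,0.000000,0.501929
13,0.468006,0.000000,0.534608
14,0.473229,0.000000,0.539839
15,0.478453,0.000000,0.545071
16,0.483676,0.000000,0.550302
17,0.488900,0.000000,0.555533
18,0.494124,0.000000,0.560765
19,0.499347,0.000000,0.565996
20,0.504571,0.000000,0.571227
21,0.509794,0.000000,0.576459
22,0.515018,0.000000,0.581690
23,0.520241,0.000000,0.586922
24,0.525465,0.000000,0.592153
25,0.530688,0.000000,0.597384
26,0.512386,0.000000,0.602616
27,0.470559,0.000000,0.607847
28,0.428731,0.000000,0.613078
29,0.386904,0.000000,0.618310
30,0.345076,0.000000,0.623541
31,0.303249,0.000000,0.628773
32,0.261422,0.000000,0.634004
33,0.219594,0.000000,0.639235
34,0.177767,0.000000,0.644467
35,0.135939,0.000000,0.649698
36,0.094112,0.000000,0.654929
37,0.052284,0.000000,0.660161
38,0.010457,0.000000,0.665392
39,0.000000,0.000000,0.678465
40,0.000000,0.000000,0.694151
41,0.000000,0.000000,0.709837
42,0.000000,0.000000,0.725524
43,0.000000,0.000000,0.741210
44,0.000000,0.000000,0.756896
45,0.000000,0.000000,0.772582
46,0.000000,0.000000,0.788269
47,0.000000,0.000000,0.803955
48,0.000000,0.000000,0.819641
49,0.000000,0.000000,0.835327
50,0.000000,0.000000,0.851014
51,0.000000,0.000000,0.866700
52,0.000000,0.036604,0.866700
53,0.000000,0.073208,0.866700
54,0.000000,0.109812,0.866700
55,0.000000,0.146416,0.866700
56,0.000000,0.183020,0.866700
57,0.000000,0.219624,0.866700
58,0.000000,0.256227,0.866700
59,0.000000,0.292831,0.866700
60,0.000000,0.329435,0.866700
61,0.000000,0.366039,0.866700
62,0.000000,0.402643,0.866700
63,0.000000,0.439247,0.866700
64,0.000000,0.469314,0.866700
65,0.000000,0.479769,0.866700
66,0.000000,0.490224,0.866700
67,0.000000,0.500678,0.866700
68,0.000000,0.511133,0.866700
69,0.000000,0.521588,0.866700
70,0.000000,0.532043,0.866700
71,0.000000,0.542498,0.866700
72,0.000000,0.552953,0.866700
73,0.000000,0.563408,0.866700
74,0.000000,0.573863,0.866700
75,0.000000,0.584318,0.866700
76,0.000000,0.594773,0.866700
77,0.000000,0.602616,0.858857
78,0.000000,0.607847,0.843171
79,0.000000,0.613078,0.827484
80,0.000000,0.618310,0.811798
81,0.000000,0.623541,0.796112
82,0.000000,0.628773,0.780425
83,0.000000,0.634004,0.764739
84,0.000000,0.639235,0.749053
85,0.000000,0.644467,0.733367
86,0.000000,0.649698,0.717680
87,0.000000,0.654929,0.701994
88,0.000000,0.660161,0.686308
89,0.000000,0.665392,0.670622
90,0.000000,0.666700,0.658853
91,0.000000,0.666700,0.648390
92,0.000000,0.666700,0.637927
93,0.000000,0.666700,0.627465
94,0.000000,0.666700,0.617002
95,0.000000,0.666700,0.606539
96,0.000000,0.666700,0.596076
97,0.000000,0.666700,0.585614
98,0.000000,0.666700,0.575151
99,0.000000,0.666700,0.564688
100,0.000000,0.666700,0.554225
101,0.000000,0.666700,0.543763
102,0.000000,0.666700,0.533300
103,0.000000,0.661469,0.491473
104,0.000000,0.656237,0.449645
105,0.000000,0.651006,0.407818
106,0.000000,0.645775,0.365990
107,0.000000,0.640543,0.324163
108,0.000000,0.635312,0.282335
109,0.000000,0.630080,0.240508
110,0.000000,0.624849,0.198680
111,0.000000,0.619618,0.156853
112,0.000000,0.614386,0.115025
113,0.000000,0.609155,0.073198
114,0.000000,0.603924,0.031371
115,0.000000,0.602614,0.000000
116,0.000000,0.613069,0.000000
117,0.000000,0.623524,0.000000
118,0.000000,0.633978,0.000000
119,0.000000,0.644433,0.000000
120,0.000000,0.654888,0.000000
121,0.000000,0.665343,0.000000
122,0.000000,0.675798,0.000000
123,0.000000,0.686253,0.000000
124,0.000000,0.696708,0.000000
125,0.000000,0.707163,0.000000
126,0.000000,0.717618,0.000000
127,0.000000,0.728073,0.000000
128,0.000000,0.738531,0.000000
129,0.000000,0.748994,0.000000
130,0.000000,0.759457,0.000000
131,0.000000,0.769920,0.000000
132,0.000000,0.780382,0.000000
133,0.000000,0.790845,0.000000
134,0.000000,0.801308,0.000000
135,0.000000,0.811771,0.000000
136,0.000000,0.822233,0.000000
137,0.000000,0.832696,0.000000
138,0.000000,0.843159,0.000000
139,0.000000,0.853622,0.000000
140,0.000000,0.864084,0.000000
141,0.000000,0.874541,0.000000
142,0.000000,0.884996,0.000000
143,0.000000,0.895451,0.000000
144,0.000000,0.905906,0.000000
145,0.000000,0.916361,0.000000
146,0.000000,0.926816,0.000000
147,0.000000,0.937271,0.000000
148,0.000000,0.947725,0.000000
149,0.000000,0.958180,0.000000
150,0.000000,0.968635,0.000000
151,0.000000,0.979090,0.000000
152,0.000000,0.989545,0.000000
153,0.000000,1.000000,0.000000
154,0.057514,1.000000,0.000000
155,0.115027,1.000000,0.000000
156,0.172541,1.000000,0.000000
157,0.230055,1.000000,0.000000
158,0.287569,1.000000,0.000000
159,0.345082,1.000000,0.000000
160,0.402596,1.000000,0.000000
161,0.460110,1.000000,0.000000
162,0.517624,1.000000,0.000000
163,0.575137,1.000000,0.000000
164,0.632651,1.000000,0.000000
165,0.690165,1.000000,0.000000
166,0.737222,0.998692,0.000000
167,0.752908,0.993461,0.000000
168,0.768594,0.988229,0.000000
169,0.784280,0.982998,0.000000
170,0.799967,0.977767,0.000000
171,0.815653,0.972535,0.000000
172,0.831339,0.967304,0.000000
173,0.847025,0.962073,0.000000
174,0.862712,0.956841,0.000000
175,0.878398,0.951610,0.000000
176,0.894084,0.946378,0.000000
177,0.909771,0.941147,0.000000
178,0.925457,0.935916,0.000000
179,0.935916,0.928073,0.000000
180,0.941147,0.917618,0.000000
181,0.946378,0.907163,0.000000
182,0.951610,0.896708,0.000000
183,0.956841,0.886253,0.000000
184,0.962073,0.875798,0.000000
185,0.967304,0.865343,0.000000
186,0.972535,0.854888,0.000000
187,0.977767,0.844433,0.000000
188,0.982998,0.833978,0.000000
189,0.988229,0.823524,0.000000
190,0.993461,0.813069,0.000000
191,0.998692,0.802614,0.000000
192,1.000000,0.788235,0.000000
193,1.000000,0.772549,0.000000
194,1.000000,0.756863,0.000000
195,1.000000,0.741176,0.000000
196,1.000000,0.725490,0.000000
197,1.000000,0.709804,0.000000
198,1.000000,0.694118,0.000000
199,1.000000,0.678431,0.000000
200,1.000000,0.662745,0.000000
201,1.000000,0.647059,0.000000
202,1.000000,0.631373,0.000000
203,1.000000,0.615686,0.000000
204,1.000000,0.600000,0.000000
205,1.000000,0.552941,0.000000
206,1.000000,0.505882,0.000000
207,1.000000,0.458824,0.000000
208,1.000000,0.411765,0.000000
209,1.000000,0.364706,0.000000
210,1.000000,0.317647,0.000000
211,1.000000,0.270588,0.000000
212,1.000000,0.223529,0.000000
213,1.000000,0.176471,0.000000
214,1.000000,0.129412,0.000000
215,1.000000,0.082353,0.000000
216,1.000000,0.035294,0.000000
217,0.997386,0.000000,0.000000
218,0.986931,0.000000,0.000000
219,0.976476,0.000000,0.000000
220,0.966022,0.000000,0.000000
221,0.955567,0.000000,0.000000
222,0.945112,0.000000,0.000000
223,0.934657,0.000000,0.000000
224,0.924202,0.000000,0.000000
225,0.913747,0.000000,0.000000
226,0.903292,0.000000,0.000000
227,0.892837,0.000000,0.000000
228,0.882382,0.000000,0.000000
229,0.871927,0.000000,0.000000
230,0.864084,0.000000,0.000000
231,0.858853,0.000000,0.000000
232,0.853622,0.000000,0.000000
233,0.848390,0.000000,0.000000
234,0.843159,0.000000,0.000000
235,0.837927,0.000000,0.000000
236,0.832696,0.000000,0.000000
237,0.827465,0.000000,0.000000
238,0.822233,0.000000,0.000000
239,0.817002,0.000000,0.000000
240,0.811771,0.000000,0.000000
241,0.806539,0.000000,0.000000
242,0.801308,0.000000,0.000000
243,0.800000,0.047059,0.047059
244,0.800000,0.109804,0.109804
245,0.800000,0.172549,0.172549
246,0.800000,0.235294,0.235294
247,0.800000,0.298039,0.298039
248,0.800000,0.360784,0.360784
249,0.800000,0.423529,0.423529
250,0.800000,0.486275,0.486275
251,0.800000,0.549020,0.549020
252,0.800000,0.611765,0.611765
253,0.800000,0.674510,0.674510
254,0.800000,0.737255,0.737255
255,0.800000,0.800000,0.800000
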