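index,R,G,B
0,0.000000,0.000000,0.300000
1,0.000000,0.000000,0.310980
2,0.000000,0.000000,0.321961
3,0.000000,0.000000,0.332941
4,0.000000,0.000000,0.343922
5,0.000000,0.000000,0.354902
6,0.000000,0.000000,0.365882
7,0.000000,0.000000,0.376863
8,0.000000,0.000000,0.387843
9,0.000000,0.000000,0.398824
10,0.000000,0.000000,0.409804
11,0.000000,0.000000,0.420784
12,0.000000,0.000000,0.431765
13,0.000000,0.000000,0.442745
14,0.000000,0.000000,0.453725
15,0.000000,0.000000,0.464706
16,0.000000,0.000000,0.475686
17,0.000000,0.000000,0.486667
18,0.000000,0.000000,0.497647
19,0.000000,0.000000,0.508627
20,0.000000,0.000000,0.519608
21,0.000000,0.000000,0.530588
22,0.000000,0.000000,0.541569
23,0.000000,0.000000,0.552549
24,0.000000,0.000000,0.563529
25,0.000000,0.000000,0.574510
26,0.000000,0.000000,0.585490
27,0.000000,0.000000,0.596471
28,0.000000,0.000000,0.607451
29,0.000000,0.000000,0.618431
30,0.000000,0.000000,0.629412
31,0.000000,0.000000,0.640392
32,0.000000,0.000000,0.651373
33,0.000000,0.000000,0.662353
34,0.000000,0.000000,0.673333
35,0.000000,0.000000,0.684314
36,0.000000,0.000000,0.695294
37,0.000000,0.000000,0.706275
38,0.000000,0.000000,0.717255
39,0.000000,0.000000,0.728235
40,0.000000,0.000000,0.739216
41,0.000000,0.000000,0.750196
42,0.000000,0.000000,0.761176
43,0.000000,0.000000,0.772157
44,0.000000,0.000000,0.783137
45,0.000000,0.000000,0.794118
46,0.000000,0.000000,0.805098
47,0.000000,0.000000,0.816078
48,0.000000,0.000000,0.827059
49,0.000000,0.000000,0.838039
50,0.000000,0.000000,0.849020
51,0.000000,0.000000,0.860000
52,0.000000,0.000000,0.870980
53,0.000000,0.000000,0.881961
54,0.000000,0.000000,0.892941
55,0.000000,0.000000,0.903922
56,0.000000,0.000000,0.914902
57,0.000000,0.000000,0.925882
58,0.000000,0.000000,0.936863
59,0.000000,0.000000,0.947843
60,0.000000,0.000000,0.958824
61,0.000000,0.000000,0.969804
62,0.000000,0.000000,0.980784
63,0.000000,0.000000,0.991765
64,0.003922,0.003922,1.000000
65,0.019608,0.019608,1.000000
66,0.035294,0.035294,1.000000
67,0.050980,0.050980,1.000000
68,0.066667,0.066667,1.000000
69,0.082353,0.082353,1.000000
70,0.098039,0.098039,1.000000
71,0.113725,0.113725,1.000000
72,0.129412,0.129412,1.000000
73,0.145098,0.145098,1.000000
74,0.160784,0.160784,1.000000
75,0.176471,0.176471,1.000000
76,0.192157,0.192157,1.000000
77,0.207843,0.207843,1.000000
78,0.223529,0.223529,1.000000
79,0.239216,0.239216,1.000000
80,0.254902,0.254902,1.000000
81,0.270588,0.270588,1.000000
82,0.286275,0.286275,1.000000
83,0.301961,0.301961,1.000000
84,0.317647,0.317647,1.000000
85,0.333333,0.333333,1.000000
86,0.349020,0.349020,1.000000
87,0.364706,0.364706,1.000000
88,0.380392,0.380392,1.000000
89,0.396078,0.396078,1.000000
90,0.411765,0.411765,1.000000
91,0.427451,0.427451,1.000000
92,0.443137,0.443137,1.000000
93,0.458824,0.458824,1.000000
94,0.474510,0.474510,1.000000
95,0.490196,0.490196,1.000000
96,0.505882,0.505882,1.000000
97,0.521569,0.521569,1.000000
98,0.537255,0.537255,1.000000
99,0.552941,0.552941,1.000000
100,0.568627,0.568627,1.000000
101,0.584314,0.584314,1.000000
102,0.600000,0.600000,1.000000
103,0.615686,0.615686,1.000000
104,0.631373,0.631373,1.000000
105,0.647059,0.647059,1.000000
106,0.662745,0.662745,1.000000
107,0.678431,0.678431,1.000000
108,0.694118,0.694118,1.000000
109,0.709804,0.709804,1.000000
110,0.725490,0.725490,1.000000
111,0.741176,0.741176,1.000000
112,0.756863,0.756863,1.000000
113,0.772549,0.772549,1.000000
114,0.788235,0.788235,1.000000
115,0.803922,0.803922,1.000000
116,0.819608,0.819608,1.000000
117,0.835294,0.835294,1.000000
118,0.850980,0.850980,1.000000
119,0.866667,0.866667,1.000000
120,0.882353,0.882353,1.000000
121,0.898039,0.898039,1.000000
122,0.913725,0.913725,1.000000
123,0.929412,0.929412,1.000000
124,0.945098,0.945098,1.000000
125,0.960784,0.960784,1.000000
126,0.976471,0.976471,1.000000
127,0.992157,0.992157,1.000000
128,1.000000,0.992157,0.992157
129,1.000000,0.976471,0.976471
130,1.000000,0.960784,0.960784
131,1.000000,0.945098,0.945098
132,1.000000,0.929412,0.929412
133,1.000000,0.913725,0.913725
134,1.000000,0.898039,0.898039
135,1.000000,0.882353,0.882353
136,1.000000,0.866667,0.866667
137,1.000000,0.850980,0.850980
138,1.000000,0.835294,0.835294
139,1.000000,0.819608,0.819608
140,1.000000,0.803922,0.803922
141,1.000000,0.788235,0.788235
142,1.000000,0.772549,0.772549
143,1.000000,0.756863,0.756863
144,1.000000,0.741176,0.741176
145,1.000000,0.725490,0.725490
146,1.000000,0.709804,0.709804
147,1.000000,0.694118,0.694118
148,1.000000,0.678431,0.678431
149,1.000000,0.662745,0.662745
150,1.000000,0.647059,0.647059
151,1.000000,0.631373,0.631373
152,1.000000,0.615686,0.615686
153,1.000000,0.600000,0.600000
154,1.000000,0.584314,0.584314
155,1.000000,0.568627,0.568627
156,1.000000,0.552941,0.552941
157,1.000000,0.537255,0.537255
158,1.000000,0.521569,0.521569
159,1.000000,0.505882,0.505882
160,1.000000,0.490196,0.490196
161,1.000000,0.474510,0.474510
162,1.000000,0.458824,0.458824
163,1.000000,0.443137,0.443137
164,1.000000,0.427451,0.427451
165,1.000000,0.411765,0.411765
166,1.000000,0.396078,0.396078
167,1.000000,0.380392,0.380392
168,1.000000,0.364706,0.364706
169,1.000000,0.349020,0.349020
170,1.000000,0.333333,0.333333
171,1.000000,0.317647,0.317647
172,1.000000,0.301961,0.301961
173,1.000000,0.286275,0.286275
174,1.000000,0.270588,0.270588
175,1.000000,0.254902,0.254902
176,1.000000,0.239216,0.239216
177,1.000000,0.223529,0.223529
178,1.000000,0.207843,0.207843
179,1.000000,0.192157,0.192157
180,1.000000,0.176471,0.176471
181,1.000000,0.160784,0.160784
182,1.000000,0.145098,0.145098
183,1.000000,0.129412,0.129412
184,1.000000,0.113725,0.113725
185,1.000000,0.098039,0.098039
186,1.000000,0.082353,0.082353
187,1.000000,0.066667,0.066667
188,1.000000,0.050980,0.050980
189,1.000000,0.035294,0.035294
190,1.000000,0.019608,0.019608
191,1.000000,0.003922,0.003922
192,0.994118,0.000000,0.000000
193,0.986275,0.000000,0.000000
194,0.978431,0.000000,0.000000
195,0.970588,0.000000,0.000000
196,0.962745,0.000000,0.000000
197,0.954902,0.000000,0.000000
198,0.947059,0.000000,0.000000
199,0.939216,0.000000,0.000000
200,0.931373,0.000000,0.000000
201,0.923529,0.000000,0.000000
202,0.915686,0.000000,0.000000
203,0.907843,0.000000,0.000000
204,0.900000,0.000000,0.000000
205,0.892157,0.000000,0.000000
206,0.884314,0.000000,0.000000
207,0.876471,0.000000,0.000000
208,0.868627,0.000000,0.000000
209,0.860784,0.000000,0.000000
210,0.852941,0.000000,0.000000
211,0.845098,0.000000,0.000000
212,0.837255,0.000000,0.000000
213,0.829412,0.000000,0.000000
214,0.821569,0.000000,0.000000
215,0.813725,0.000000,0.000000
216,0.805882,0.000000,0.000000
217,0.798039,0.000000,0.000000
218,0.790196,0.000000,0.000000
219,0.782353,0.000000,0.000000
220,0.774510,0.000000,0.000000
221,0.766667,0.000000,0.000000
222,0.758824,0.000000,0.000000
223,0.750980,0.000000,0.000000
224,0.743137,0.000000,0.000000
225,0.735294,0.000000,0.000000
226,0.727451,0.000000,0.000000
227,0.719608,0.000000,0.000000
228,0.711765,0.000000,0.000000
229,0.703922,0.000000,0.000000
230,0.696078,0.000000,0.000000
231,0.688235,0.000000,0.000000
232,0.680392,0.000000,0.000000
233,0.672549,0.000000,0.000000
234,0.664706,0.000000,0.000000
235,0.656863,0.000000,0.000000
236,0.649020,0.000000,0.000000
237,0.641176,0.000000,0.000000
238,0.633333,0.000000,0.000000
239,0.625490,0.000000,0.000000
240,0.617647,0.000000,0.000000
241,0.609804,0.000000,0.000000
242,0.601961,0.000000,0.000000
243,0.594118,0.000000,0.000000
244,0.586275,0.000000,0.000000
245,0.578431,0.000000,0.000000
246,0.570588,0.000000,0.000000
247,0.562745,0.000000,0.000000
248,0.554902,0.000000,0.000000
249,0.547059,0.000000,0.000000
250,0.539216,0.000000,0.000000
251,0.531373,0.000000,0.000000
252,0.523529,0.000000,0.000000
253,0.515686,0.000000,0.000000
254,0.507843,0.000000,0.000000
255,0.500000,0.000000,0.000000
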