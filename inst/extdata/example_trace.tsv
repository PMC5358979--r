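frame	donor	acceptor
0	308	153
1	219	201
2	201	243
3	217	217
4	203	260
5	177	246
6	202	248
7	188	233
8	218	202
9	233	184
10	363	135
11	306	131
12	315	121
13	297	135
14	312	125
15	298	116
16	343	124
17	258	143
18	228	227
19	192	249
20	224	206
21	187	277
22	201	217
23	223	219
24	213	245
25	148	271
26	194	207
27	182	269
28	191	232
29	201	244
30	247	218
31	184	267
32	186	239
33	174	256
34	171	233
35	205	187
36	197	205
37	197	208
38	229	168
39	198	206
40	167	276
41	248	180
42	204	234
43	190	240
44	203	218
45	201	249
46	230	208
47	200	219
48	164	209
49	241	214
50	194	234
51	189	272
52	193	252
53	212	263
54	188	271
55	221	220
56	163	256
57	203	236
58	153	256
59	212	186
60	232	207
61	140	291
62	181	246
63	178	249
64	210	242
65	210	237
66	273	176
67	178	210
68	213	207
69	158	280
70	198	204
71	159	267
72	197	216
73	172	245
74	212	218
75	226	199
76	201	243
77	197	193
78	208	206
79	218	232
80	215	220
81	184	249
82	220	203
83	205	239
84	243	198
85	190	297
86	187	221
87	214	205
88	188	255
89	212	219
90	199	244
91	173	245
92	156	230
93	212	206
94	203	255
95	205	266
96	219	216
97	280	154
98	317	120
99	373	86
100	326	123
101	264	176
102	289	130
103	297	154
104	320	92
105	341	125
106	328	102
107	309	117
108	298	130
109	318	105
110	284	118
111	313	131
112	200	262
113	209	206
114	202	253
115	224	252
116	207	227
117	251	203
118	198	235
119	223	200
120	174	231
121	189	270
122	225	244
123	198	258
124	299	119
125	274	106
126	306	104
127	227	184
128	156	229
129	205	215
130	177	246
131	204	200
132	161	224
133	215	195
134	189	242
135	183	223
136	242	200
137	171	240
138	166	235
139	278	156
140	290	106
141	327	76
142	304	110
143	303	131
144	320	96
145	362	106
146	322	113
147	258	187
148	194	269
149	202	232
150	249	183
151	260	176
152	179	237
153	213	235
154	206	237
155	202	240
156	185	225
157	189	260
158	222	206
159	254	193
160	179	247
161	246	211
162	245	211
163	221	235
164	200	226
165	212	195
166	202	230
167	172	234
168	201	223
169	88	91
170	13	12
171	14	20
172	10	15
173	12	19
174	20	13
175	8	12
176	15	20
177	15	13
178	13	12
179	12	13
180	22	15
181	13	14
182	18	13
183	13	7
184	13	20
185	6	15
186	14	15
187	13	15
188	19	15
189	13	12
190	10	15
191	17	16
192	16	17
193	11	13
194	15	16
195	8	7
196	16	16
197	12	21
198	12	14
199	11	27
200	22	14
201	19	24
202	15	21
203	18	7
204	20	16
205	18	16
206	17	20
207	18	7
208	8	20
209	18	9
210	25	14
211	12	13
212	13	12
213	20	12
214	21	16
215	14	16
216	11	18
217	16	15
218	22	15
219	18	7
220	11	17
221	15	10
222	26	16
223	18	20
224	13	10
225	16	12
226	10	17
227	19	12
228	14	15
229	12	16
230	7	20
231	18	19
232	18	21
233	14	25
234	17	17
235	16	12
236	13	11
237	10	11
238	24	12
239	18	19
240	14	11
241	11	11
242	14	13
243	16	12
244	10	18
245	13	13
246	15	14
247	10	17
248	11	9
249	11	17
250	12	18
251	11	17
252	14	18
253	10	11
254	14	14
255	20	16
256	10	20
257	7	21
258	12	7
259	14	11
260	14	16
261	11	16
262	19	16
263	21	10
264	12	12
265	13	11
266	11	17
267	16	25
268	15	10
269	14	8
270	12	15
271	9	18
272	11	12
273	13	13
274	15	11
275	10	21
276	20	16
277	22	19
278	7	19
279	25	15
280	17	17
281	17	11
282	13	19
283	12	7
284	14	12
285	16	20
286	15	19
287	14	11
288	17	14
289	17	22
290	13	20
291	20	15
292	12	16
293	17	16
294	21	9
295	19	11
296	11	13
297	16	15
298	11	12
299	20	11
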