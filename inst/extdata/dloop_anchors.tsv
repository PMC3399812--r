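snp_no	align_pos	rcrs_pos	iupac
1	51	16051	R
2	86	16086	Y
3	92	16092	H
4	93	16093	Y
5	108	16108	Y
6	111	16111	Y
7	126	16126	Y
8	129	16129	R
9	136	16136	Y
10	140	16140	Y
11	145	16145	R
12	148	16148	Y
13	157	16157	Y
14	162	16162	R
15	164	16164	R
16	167	16167	Y
17	172	16172	Y
18	209	16209	Y
19	217	16217	Y
20	218	16218	Y
21	223	16223	Y
22	227	16227	R
23	234	16234	Y
24	235	16235	R
25	243	16243	H
26	248	16248	Y
27	249	16249	Y
28	256	16256	Y
29	257	16257	H
30	260	16260	Y
31	261	16261	Y
32	266	16266	N
33	272	16272	R
34	274	16274	R
35	278	16278	Y
36	290	16290	Y
37	291	16291	Y
38	295	16295	Y
39	297	16297	Y
40	298	16298	Y
41	304	16304	Y
42	309	16309	R
43	311	16311	Y
44	316	16316	R
45	319	16319	R
46	324	16324	Y
47	327	16327	Y
48	335	16335	R
49	355	16355	Y
50	356	16356	Y
51	357	16357	Y
52	362	16362	Y
53	390	16390	R
54	399	16399	R
55	463	16463	R
56	519	16519	Y
57	662	93	R
58	672	103	R
59	715	146	H
60	719	150	Y
61	720	151	Y
62	721	152	Y
63	722	153	R
64	754	185	R
65	758	189	R
66	763	194	Y
67	764	195	Y
68	768	199	Y
69	769	200	R
70	773	204	Y
71	776	207	R
72	779	210	R
73	786	217	Y
74	803	234	R
75	804	235	R
76	885	317	Y
77	1019	461	Y
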