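id	kind	dye	size_min	size_max	motif	anchor_size	anchor_count	indel_size	multiplex	gel_scored
1	unknown	NED	121	124	NA	NA	NA	NA	A-1	FALSE
2	unknown	HEX	148	150	NA	NA	NA	NA	B-1	FALSE
3	unknown	none	NA	NA	NA	NA	NA	NA	NA	FALSE
4	unknown	none	NA	NA	NA	NA	NA	NA	NA	FALSE
5	unknown	none	NA	NA	NA	NA	NA	NA	NA	FALSE
6	unknown	6-FAM	173	174	NA	NA	NA	NA	C-2	FALSE
7	unknown	none	NA	NA	NA	NA	NA	NA	NA	FALSE
8	indel	none	NA	NA	NA	NA	NA	225	NA	TRUE
9	unknown	NED	135	136	NA	NA	NA	NA	A-1	FALSE
10	mixed	none	NA	NA	NA	NA	NA	NA	standalone	FALSE
11	mixed	HEX	126	136	NA	NA	NA	NA	B-1	FALSE
12	unknown	none	NA	NA	NA	NA	NA	NA	NA	FALSE
13	unknown	none	NA	NA	NA	NA	NA	NA	NA	FALSE
14	unknown	none	NA	NA	NA	NA	NA	NA	NA	FALSE
15	unknown	6-FAM	137	138	NA	NA	NA	NA	C-1	FALSE
16	unknown	none	NA	NA	NA	NA	NA	NA	NA	FALSE
17	unknown	NED	178	179	NA	NA	NA	NA	A-2	FALSE
18	unknown	none	NA	NA	NA	NA	NA	NA	NA	FALSE
19	unknown	none	NA	NA	NA	NA	NA	NA	separate	FALSE
20	unknown	none	NA	NA	NA	NA	NA	NA	NA	FALSE
21	unknown	6-FAM	103	104	NA	NA	NA	NA	C-1	FALSE
22	unknown	NED	158	159	NA	NA	NA	NA	A-1	FALSE
23	unknown	HEX	120	121	NA	NA	NA	NA	B-1	FALSE
24	unknown	6-FAM	187	189	NA	NA	NA	NA	C-2	FALSE
25	unknown	HEX	174	177	NA	NA	NA	NA	B-2	FALSE
26	unknown	none	NA	NA	NA	NA	NA	NA	NA	FALSE
27	unknown	HEX	112	113	NA	NA	NA	NA	B-1	FALSE
28	unknown	NED	182	183	NA	NA	NA	NA	A-2	FALSE
29	unknown	6-FAM	203	204	NA	NA	NA	NA	C-2	FALSE
30	unknown	none	NA	NA	NA	NA	NA	NA	NA	FALSE
31	unknown	6-FAM	131	133	NA	NA	NA	NA	C-1	FALSE
32	unknown	none	NA	NA	NA	NA	NA	NA	NA	FALSE
33	unknown	NED	235	236	NA	NA	NA	NA	A-2	FALSE
34	unknown	none	NA	NA	NA	NA	NA	NA	NA	FALSE
35	unknown	none	NA	NA	NA	NA	NA	NA	NA	FALSE
36	unknown	HEX	182	183	NA	NA	NA	NA	B-2	FALSE
37	unknown	none	NA	NA	NA	NA	NA	NA	NA	FALSE
38	unknown	6-FAM	109	111	NA	NA	NA	NA	C-1	FALSE
39	unknown	HEX	105	106	NA	NA	NA	NA	B-1	FALSE
40	unknown	none	NA	NA	NA	NA	NA	NA	NA	FALSE
41	unknown	NED	169	171	NA	NA	NA	NA	A-1	FALSE
42	unknown	HEX	137	139	NA	NA	NA	NA	B-1	FALSE
43	unknown	none	NA	NA	NA	NA	NA	NA	NA	FALSE
44	unknown	none	NA	NA	NA	NA	NA	NA	NA	FALSE
45	unknown	none	NA	NA	NA	NA	NA	NA	NA	FALSE
46	unknown	NED	110	112	NA	NA	NA	NA	A-1	FALSE
47	unknown	6-FAM	154	157	NA	NA	NA	NA	C-1	FALSE
48	unknown	HEX	158	159	NA	NA	NA	NA	B-2	FALSE
49	unknown	6-FAM	181	182	NA	NA	NA	NA	C-2	FALSE
50	unknown	NED	227	228	NA	NA	NA	NA	A-2	FALSE
51	unknown	NED	139	146	NA	NA	NA	NA	A-1	FALSE
52	unknown	HEX	191	203	NA	NA	NA	NA	B-2	FALSE
53	unknown	NED	203	204	NA	NA	NA	NA	A-2	FALSE
54	mixed	6-FAM	231	239	NA	NA	NA	NA	C-2	FALSE
55	unknown	none	NA	NA	NA	NA	NA	NA	NA	FALSE
56	unknown	NED	188	190	NA	NA	NA	NA	A-2	FALSE
57	mixed	6-FAM	224	227	NA	NA	NA	NA	C-2	FALSE
58	unknown	HEX	234	236	NA	NA	NA	NA	B-2	FALSE
59	unknown	6-FAM	164	165	NA	NA	NA	NA	C-1	FALSE
60	unknown	none	NA	NA	NA	NA	NA	NA	NA	FALSE
61	indel	none	NA	NA	NA	NA	NA	342	NA	TRUE
62	unknown	none	NA	NA	NA	NA	NA	NA	NA	FALSE
63	unknown	none	NA	NA	NA	NA	NA	NA	NA	FALSE
64	unknown	none	NA	NA	NA	NA	NA	NA	NA	FALSE
CAPS-XapI	caps	none	NA	NA	NA	NA	NA	NA	separate	FALSE
CAPS-EcoRI	caps	none	NA	NA	NA	NA	NA	NA	separate	FALSE
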