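probeset_id	probe_id	x	y	is_core
PS00001	1	0	0	TRUE
PS00002	2	1	0	TRUE
PS00003	3	2	0	TRUE
PS00004	4	3	0	TRUE
PS00005	5	4	0	TRUE
PS00006	6	5	0	TRUE
PS00007	7	6	0	TRUE
PS00008	8	7	0	TRUE
PS00009	9	8	0	TRUE
PS00010	10	9	0	TRUE
PS00011	11	10	0	TRUE
PS00012	12	11	0	TRUE
PS00013	13	12	0	TRUE
PS00014	14	13	0	TRUE
PS00015	15	14	0	TRUE
PS00016	16	15	0	TRUE
PS00017	17	0	1	TRUE
PS00018	18	1	1	TRUE
PS00019	19	2	1	TRUE
PS00020	20	3	1	TRUE
PS00021	21	4	1	TRUE
PS00022	22	5	1	TRUE
PS00023	23	6	1	TRUE
PS00024	24	7	1	TRUE
PS00025	25	8	1	TRUE
PS00026	26	9	1	TRUE
PS00027	27	10	1	TRUE
PS00028	28	11	1	TRUE
PS00029	29	12	1	TRUE
PS00030	30	13	1	TRUE
PS00031	31	14	1	TRUE
PS00032	32	15	1	TRUE
PS00033	33	0	2	TRUE
PS00034	34	1	2	TRUE
PS00035	35	2	2	TRUE
PS00036	36	3	2	TRUE
PS00037	37	4	2	TRUE
PS00038	38	5	2	TRUE
PS00039	39	6	2	TRUE
PS00040	40	7	2	TRUE
PS00041	41	8	2	TRUE
PS00042	42	9	2	TRUE
PS00043	43	10	2	TRUE
PS00044	44	11	2	TRUE
PS00045	45	12	2	TRUE
PS00046	46	13	2	TRUE
PS00047	47	14	2	TRUE
PS00048	48	15	2	TRUE
PS00049	49	0	3	TRUE
PS00050	50	1	3	TRUE
PS00051	51	2	3	TRUE
PS00052	52	3	3	TRUE
PS00053	53	4	3	TRUE
PS00054	54	5	3	TRUE
PS00055	55	6	3	TRUE
PS00056	56	7	3	TRUE
PS00057	57	8	3	TRUE
PS00058	58	9	3	TRUE
PS00059	59	10	3	TRUE
PS00060	60	11	3	TRUE
PS00061	61	12	3	TRUE
PS00062	62	13	3	TRUE
PS00063	63	14	3	TRUE
PS00064	64	15	3	TRUE
PS00001	65	0	4	TRUE
PS00002	66	1	4	TRUE
PS00003	67	2	4	TRUE
PS00004	68	3	4	TRUE
PS00005	69	4	4	TRUE
PS00006	70	5	4	TRUE
PS00007	71	6	4	TRUE
PS00008	72	7	4	TRUE
PS00009	73	8	4	TRUE
PS00010	74	9	4	TRUE
PS00011	75	10	4	TRUE
PS00012	76	11	4	TRUE
PS00013	77	12	4	TRUE
PS00014	78	13	4	TRUE
PS00015	79	14	4	TRUE
PS00016	80	15	4	TRUE
PS00017	81	0	5	TRUE
PS00018	82	1	5	TRUE
PS00019	83	2	5	TRUE
PS00020	84	3	5	TRUE
PS00021	85	4	5	TRUE
PS00022	86	5	5	TRUE
PS00023	87	6	5	TRUE
PS00024	88	7	5	TRUE
PS00025	89	8	5	TRUE
PS00026	90	9	5	TRUE
PS00027	91	10	5	TRUE
PS00028	92	11	5	TRUE
PS00029	93	12	5	TRUE
PS00030	94	13	5	TRUE
PS00031	95	14	5	TRUE
PS00032	96	15	5	TRUE
PS00033	97	0	6	TRUE
PS00034	98	1	6	TRUE
PS00035	99	2	6	TRUE
PS00036	100	3	6	TRUE
PS00037	101	4	6	TRUE
PS00038	102	5	6	TRUE
PS00039	103	6	6	TRUE
PS00040	104	7	6	TRUE
PS00041	105	8	6	TRUE
PS00042	106	9	6	TRUE
PS00043	107	10	6	TRUE
PS00044	108	11	6	TRUE
PS00045	109	12	6	TRUE
PS00046	110	13	6	TRUE
PS00047	111	14	6	TRUE
PS00048	112	15	6	TRUE
PS00049	113	0	7	TRUE
PS00050	114	1	7	TRUE
PS00051	115	2	7	TRUE
PS00052	116	3	7	TRUE
PS00053	117	4	7	TRUE
PS00054	118	5	7	TRUE
PS00055	119	6	7	TRUE
PS00056	120	7	7	TRUE
PS00057	121	8	7	TRUE
PS00058	122	9	7	TRUE
PS00059	123	10	7	TRUE
PS00060	124	11	7	TRUE
PS00061	125	12	7	TRUE
PS00062	126	13	7	TRUE
PS00063	127	14	7	TRUE
PS00064	128	15	7	TRUE
PS00001	129	0	8	TRUE
PS00002	130	1	8	TRUE
PS00003	131	2	8	TRUE
PS00004	132	3	8	TRUE
PS00005	133	4	8	TRUE
PS00006	134	5	8	TRUE
PS00007	135	6	8	TRUE
PS00008	136	7	8	TRUE
PS00009	137	8	8	TRUE
PS00010	138	9	8	TRUE
PS00011	139	10	8	TRUE
PS00012	140	11	8	TRUE
PS00013	141	12	8	TRUE
PS00014	142	13	8	TRUE
PS00015	143	14	8	TRUE
PS00016	144	15	8	TRUE
PS00017	145	0	9	TRUE
PS00018	146	1	9	TRUE
PS00019	147	2	9	TRUE
PS00020	148	3	9	TRUE
PS00021	149	4	9	TRUE
PS00022	150	5	9	TRUE
PS00023	151	6	9	TRUE
PS00024	152	7	9	TRUE
PS00025	153	8	9	TRUE
PS00026	154	9	9	TRUE
PS00027	155	10	9	TRUE
PS00028	156	11	9	TRUE
PS00029	157	12	9	TRUE
PS00030	158	13	9	TRUE
PS00031	159	14	9	TRUE
PS00032	160	15	9	TRUE
PS00033	161	0	10	TRUE
PS00034	162	1	10	TRUE
PS00035	163	2	10	TRUE
PS00036	164	3	10	TRUE
PS00037	165	4	10	TRUE
PS00038	166	5	10	TRUE
PS00039	167	6	10	TRUE
PS00040	168	7	10	TRUE
PS00041	169	8	10	TRUE
PS00042	170	9	10	TRUE
PS00043	171	10	10	TRUE
PS00044	172	11	10	TRUE
PS00045	173	12	10	TRUE
PS00046	174	13	10	TRUE
PS00047	175	14	10	TRUE
PS00048	176	15	10	TRUE
PS00049	177	0	11	TRUE
PS00050	178	1	11	TRUE
PS00051	179	2	11	TRUE
PS00052	180	3	11	TRUE
PS00053	181	4	11	TRUE
PS00054	182	5	11	TRUE
PS00055	183	6	11	TRUE
PS00056	184	7	11	TRUE
PS00057	185	8	11	TRUE
PS00058	186	9	11	TRUE
PS00059	187	10	11	TRUE
PS00060	188	11	11	TRUE
PS00061	189	12	11	TRUE
PS00062	190	13	11	TRUE
PS00063	191	14	11	TRUE
PS00064	192	15	11	TRUE
PS00001	193	0	12	TRUE
PS00002	194	1	12	TRUE
PS00003	195	2	12	TRUE
PS00004	196	3	12	TRUE
PS00005	197	4	12	TRUE
PS00006	198	5	12	TRUE
PS00007	199	6	12	TRUE
PS00008	200	7	12	TRUE
PS00009	201	8	12	TRUE
PS00010	202	9	12	TRUE
PS00011	203	10	12	TRUE
PS00012	204	11	12	TRUE
PS00013	205	12	12	TRUE
PS00014	206	13	12	TRUE
PS00015	207	14	12	TRUE
PS00016	208	15	12	TRUE
PS00017	209	0	13	TRUE
PS00018	210	1	13	TRUE
PS00019	211	2	13	TRUE
PS00020	212	3	13	TRUE
PS00021	213	4	13	TRUE
PS00022	214	5	13	TRUE
PS00023	215	6	13	TRUE
PS00024	216	7	13	TRUE
PS00025	217	8	13	TRUE
PS00026	218	9	13	TRUE
PS00027	219	10	13	TRUE
PS00028	220	11	13	TRUE
PS00029	221	12	13	TRUE
PS00030	222	13	13	TRUE
PS00031	223	14	13	TRUE
PS00032	224	15	13	TRUE
PS00033	225	0	14	TRUE
PS00034	226	1	14	TRUE
PS00035	227	2	14	TRUE
PS00036	228	3	14	TRUE
PS00037	229	4	14	TRUE
PS00038	230	5	14	TRUE
PS00039	231	6	14	TRUE
PS00040	232	7	14	TRUE
PS00041	233	8	14	TRUE
PS00042	234	9	14	TRUE
PS00043	235	10	14	TRUE
PS00044	236	11	14	TRUE
PS00045	237	12	14	TRUE
PS00046	238	13	14	TRUE
PS00047	239	14	14	TRUE
PS00048	240	15	14	TRUE
PS00049	241	0	15	TRUE
PS00050	242	1	15	TRUE
PS00051	243	2	15	TRUE
PS00052	244	3	15	TRUE
PS00053	245	4	15	TRUE
PS00054	246	5	15	TRUE
PS00055	247	6	15	TRUE
PS00056	248	7	15	TRUE
PS00057	249	8	15	TRUE
PS00058	250	9	15	TRUE
PS00059	251	10	15	TRUE
PS00060	252	11	15	TRUE
PS00061	253	12	15	TRUE
PS00062	254	13	15	TRUE
PS00063	255	14	15	TRUE
PS00064	256	15	15	TRUE
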