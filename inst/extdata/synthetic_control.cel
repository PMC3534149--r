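[CEL]
Version=3

[HEADER]
Cols=16
Rows=16

[INTENSITY]
NumberCells=256
CellHeader=X	Y	MEAN	STDV	NPIXELS
0	0	475.3	0.0	1
1	0	54.3	0.0	1
2	0	391.4	0.0	1
3	0	184.7	0.0	1
4	0	79.6	0.0	1
5	0	8.7	0.0	1
6	0	86.1	0.0	1
7	0	52.5	0.0	1
8	0	255.2	0.0	1
9	0	152.3	0.0	1
10	0	129.0	0.0	1
11	0	92.3	0.0	1
12	0	164.4	0.0	1
13	0	201.8	0.0	1
14	0	6.7	0.0	1
15	0	1790.9	0.0	1
0	1	547.2	0.0	1
1	1	477.5	0.0	1
2	1	90.0	0.0	1
3	1	482.2	0.0	1
4	1	206.0	0.0	1
5	1	201.1	0.0	1
6	1	38.7	0.0	1
7	1	2484.6	0.0	1
8	1	293.6	0.0	1
9	1	5620.6	0.0	1
10	1	2574.9	0.0	1
11	1	295.0	0.0	1
12	1	680.0	0.0	1
13	1	3212.0	0.0	1
14	1	142.0	0.0	1
15	1	354.6	0.0	1
0	2	145.0	0.0	1
1	2	378.0	0.0	1
2	2	333.8	0.0	1
3	2	1180.9	0.0	1
4	2	616.3	0.0	1
5	2	64.8	0.0	1
6	2	666.9	0.0	1
7	2	84.6	0.0	1
8	2	56.6	0.0	1
9	2	724.4	0.0	1
10	2	42.8	0.0	1
11	2	504.4	0.0	1
12	2	69.4	0.0	1
13	2	1591.5	0.0	1
14	2	609.8	0.0	1
15	2	200.9	0.0	1
0	3	761.4	0.0	1
1	3	560.6	0.0	1
2	3	42.3	0.0	1
3	3	178.7	0.0	1
4	3	68.5	0.0	1
5	3	535.0	0.0	1
6	3	99.4	0.0	1
7	3	209.6	0.0	1
8	3	47.0	0.0	1
9	3	69.7	0.0	1
10	3	445.2	0.0	1
11	3	57.0	0.0	1
12	3	249.2	0.0	1
13	3	390.5	0.0	1
14	3	259.4	0.0	1
15	3	180.8	0.0	1
0	4	24.1	0.0	1
1	4	180.1	0.0	1
2	4	23.9	0.0	1
3	4	1406.7	0.0	1
4	4	60.7	0.0	1
5	4	366.6	0.0	1
6	4	583.1	0.0	1
7	4	291.2	0.0	1
8	4	2698.2	0.0	1
9	4	83.0	0.0	1
10	4	433.0	0.0	1
11	4	71.1	0.0	1
12	4	4648.6	0.0	1
13	4	581.2	0.0	1
14	4	149.0	0.0	1
15	4	774.9	0.0	1
0	5	61.1	0.0	1
1	5	2205.8	0.0	1
2	5	44.7	0.0	1
3	5	28.8	0.0	1
4	5	181.9	0.0	1
5	5	802.2	0.0	1
6	5	200.8	0.0	1
7	5	70.1	0.0	1
8	5	1543.7	0.0	1
9	5	7054.7	0.0	1
10	5	17.0	0.0	1
11	5	2157.4	0.0	1
12	5	122.5	0.0	1
13	5	961.8	0.0	1
14	5	18.5	0.0	1
15	5	167.8	0.0	1
0	6	56.5	0.0	1
1	6	148.7	0.0	1
2	6	64.0	0.0	1
3	6	372.8	0.0	1
4	6	1881.8	0.0	1
5	6	123.6	0.0	1
6	6	177.2	0.0	1
7	6	42.3	0.0	1
8	6	1024.2	0.0	1
9	6	476.4	0.0	1
10	6	31.1	0.0	1
11	6	2063.7	0.0	1
12	6	58.7	0.0	1
13	6	53.0	0.0	1
14	6	24.9	0.0	1
15	6	52.4	0.0	1
0	7	170.6	0.0	1
1	7	669.4	0.0	1
2	7	92.9	0.0	1
3	7	211.9	0.0	1
4	7	187.7	0.0	1
5	7	1195.0	0.0	1
6	7	4667.1	0.0	1
7	7	51.6	0.0	1
8	7	3690.3	0.0	1
9	7	5033.9	0.0	1
10	7	278.2	0.0	1
11	7	873.5	0.0	1
12	7	18.9	0.0	1
13	7	557.9	0.0	1
14	7	122.0	0.0	1
15	7	186.6	0.0	1
0	8	611.9	0.0	1
1	8	922.5	0.0	1
2	8	293.9	0.0	1
3	8	8689.0	0.0	1
4	8	423.5	0.0	1
5	8	164.9	0.0	1
6	8	443.9	0.0	1
7	8	216.1	0.0	1
8	8	49.0	0.0	1
9	8	480.5	0.0	1
10	8	1000.8	0.0	1
11	8	455.1	0.0	1
12	8	436.8	0.0	1
13	8	271.7	0.0	1
14	8	860.5	0.0	1
15	8	55.1	0.0	1
0	9	1108.5	0.0	1
1	9	101.2	0.0	1
2	9	473.2	0.0	1
3	9	602.9	0.0	1
4	9	301.3	0.0	1
5	9	27.9	0.0	1
6	9	264.7	0.0	1
7	9	347.5	0.0	1
8	9	901.6	0.0	1
9	9	546.8	0.0	1
10	9	597.7	0.0	1
11	9	1095.0	0.0	1
12	9	88.5	0.0	1
13	9	92.7	0.0	1
14	9	161.2	0.0	1
15	9	369.5	0.0	1
0	10	1608.0	0.0	1
1	10	75.7	0.0	1
2	10	64.3	0.0	1
3	10	813.3	0.0	1
4	10	114.8	0.0	1
5	10	252.0	0.0	1
6	10	487.2	0.0	1
7	10	117.8	0.0	1
8	10	130.4	0.0	1
9	10	158.8	0.0	1
10	10	139.4	0.0	1
11	10	87.8	0.0	1
12	10	877.4	0.0	1
13	10	144.6	0.0	1
14	10	216.2	0.0	1
15	10	259.3	0.0	1
0	11	15.3	0.0	1
1	11	446.0	0.0	1
2	11	2188.4	0.0	1
3	11	222.1	0.0	1
4	11	73.3	0.0	1
5	11	1186.2	0.0	1
6	11	413.5	0.0	1
7	11	916.5	0.0	1
8	11	390.8	0.0	1
9	11	846.6	0.0	1
10	11	2399.5	0.0	1
11	11	552.4	0.0	1
12	11	524.6	0.0	1
13	11	89.4	0.0	1
14	11	601.8	0.0	1
15	11	148.3	0.0	1
0	12	5780.3	0.0	1
1	12	412.4	0.0	1
2	12	89.1	0.0	1
3	12	2778.5	0.0	1
4	12	93.7	0.0	1
5	12	27.1	0.0	1
6	12	64.2	0.0	1
7	12	281.1	0.0	1
8	12	143.9	0.0	1
9	12	652.3	0.0	1
10	12	182.1	0.0	1
11	12	19.8	0.0	1
12	12	167.7	0.0	1
13	12	4455.2	0.0	1
14	12	124.4	0.0	1
15	12	136.8	0.0	1
0	13	263.8	0.0	1
1	13	2227.1	0.0	1
2	13	94.8	0.0	1
3	13	836.8	0.0	1
4	13	130.2	0.0	1
5	13	120.0	0.0	1
6	13	136.8	0.0	1
7	13	706.8	0.0	1
8	13	615.0	0.0	1
9	13	1125.9	0.0	1
10	13	1093.0	0.0	1
11	13	5685.5	0.0	1
12	13	330.7	0.0	1
13	13	10.2	0.0	1
14	13	134.2	0.0	1
15	13	71.4	0.0	1
0	14	133.9	0.0	1
1	14	1591.6	0.0	1
2	14	108.7	0.0	1
3	14	89.1	0.0	1
4	14	543.1	0.0	1
5	14	759.1	0.0	1
6	14	169.9	0.0	1
7	14	428.4	0.0	1
8	14	551.0	0.0	1
9	14	372.0	0.0	1
10	14	111.6	0.0	1
11	14	644.5	0.0	1
12	14	9.1	0.0	1
13	14	616.8	0.0	1
14	14	484.4	0.0	1
15	14	4475.2	0.0	1
0	15	390.7	0.0	1
1	15	293.7	0.0	1
2	15	1303.0	0.0	1
3	15	538.9	0.0	1
4	15	313.8	0.0	1
5	15	320.0	0.0	1
6	15	360.4	0.0	1
7	15	64.3	0.0	1
8	15	1441.0	0.0	1
9	15	112.9	0.0	1
10	15	175.6	0.0	1
11	15	603.9	0.0	1
12	15	166.3	0.0	1
13	15	237.6	0.0	1
14	15	2137.3	0.0	1
15	15	101.6	0.0	1
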