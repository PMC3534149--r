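[CEL]
Version=3

[HEADER]
Cols=16
Rows=16

[INTENSITY]
NumberCells=256
CellHeader=X	Y	MEAN	STDV	NPIXELS
0	0	506.5	0.0	1
1	0	74.3	0.0	1
2	0	292.6	0.0	1
3	0	206.8	0.0	1
4	0	106.2	0.0	1
5	0	8.7	0.0	1
6	0	82.5	0.0	1
7	0	60.8	0.0	1
8	0	293.3	0.0	1
9	0	112.3	0.0	1
10	0	145.8	0.0	1
11	0	124.7	0.0	1
12	0	219.6	0.0	1
13	0	164.9	0.0	1
14	0	8.0	0.0	1
15	0	1587.1	0.0	1
0	1	584.8	0.0	1
1	1	402.6	0.0	1
2	1	93.2	0.0	1
3	1	782.2	0.0	1
4	1	175.7	0.0	1
5	1	177.3	0.0	1
6	1	34.1	0.0	1
7	1	1583.0	0.0	1
8	1	304.7	0.0	1
9	1	4564.0	0.0	1
10	1	2130.0	0.0	1
11	1	281.3	0.0	1
12	1	684.5	0.0	1
13	1	2695.8	0.0	1
14	1	106.6	0.0	1
15	1	270.5	0.0	1
0	2	224.6	0.0	1
1	2	391.4	0.0	1
2	2	404.8	0.0	1
3	2	1149.3	0.0	1
4	2	728.5	0.0	1
5	2	81.6	0.0	1
6	2	572.4	0.0	1
7	2	99.8	0.0	1
8	2	48.3	0.0	1
9	2	706.8	0.0	1
10	2	48.2	0.0	1
11	2	384.9	0.0	1
12	2	78.5	0.0	1
13	2	1771.2	0.0	1
14	2	591.8	0.0	1
15	2	173.0	0.0	1
0	3	670.4	0.0	1
1	3	405.4	0.0	1
2	3	43.5	0.0	1
3	3	256.4	0.0	1
4	3	77.6	0.0	1
5	3	529.7	0.0	1
6	3	74.4	0.0	1
7	3	173.9	0.0	1
8	3	56.4	0.0	1
9	3	86.0	0.0	1
10	3	217.5	0.0	1
11	3	42.7	0.0	1
12	3	166.0	0.0	1
13	3	254.5	0.0	1
14	3	220.8	0.0	1
15	3	185.0	0.0	1
0	4	31.5	0.0	1
1	4	181.4	0.0	1
2	4	19.9	0.0	1
3	4	1673.5	0.0	1
4	4	72.9	0.0	1
5	4	355.2	0.0	1
6	4	908.7	0.0	1
7	4	248.5	0.0	1
8	4	1764.4	0.0	1
9	4	95.5	0.0	1
10	4	337.5	0.0	1
11	4	1041.0	0.0	1
12	4	4185.7	0.0	1
13	4	568.2	0.0	1
14	4	139.0	0.0	1
15	4	809.4	0.0	1
0	5	51.4	0.0	1
1	5	1708.2	0.0	1
2	5	57.1	0.0	1
3	5	32.2	0.0	1
4	5	257.4	0.0	1
5	5	884.5	0.0	1
6	5	311.3	0.0	1
7	5	79.4	0.0	1
8	5	142.9	0.0	1
9	5	8265.4	0.0	1
10	5	18.8	0.0	1
11	5	2392.7	0.0	1
12	5	132.3	0.0	1
13	5	1107.9	0.0	1
14	5	24.8	0.0	1
15	5	157.9	0.0	1
0	6	92.0	0.0	1
1	6	114.3	0.0	1
2	6	43.3	0.0	1
3	6	418.1	0.0	1
4	6	3167.3	0.0	1
5	6	114.7	0.0	1
6	6	3868.5	0.0	1
7	6	851.1	0.0	1
8	6	464.1	0.0	1
9	6	258.5	0.0	1
10	6	976.8	0.0	1
11	6	1595.0	0.0	1
12	6	788.1	0.0	1
13	6	69.5	0.0	1
14	6	28.8	0.0	1
15	6	49.3	0.0	1
0	7	176.1	0.0	1
1	7	582.8	0.0	1
2	7	104.8	0.0	1
3	7	201.0	0.0	1
4	7	183.4	0.0	1
5	7	1011.2	0.0	1
6	7	280.9	0.0	1
7	7	1911.7	0.0	1
8	7	321.9	0.0	1
9	7	368.8	0.0	1
10	7	502.6	0.0	1
11	7	1012.0	0.0	1
12	7	746.6	0.0	1
13	7	513.1	0.0	1
14	7	96.0	0.0	1
15	7	221.7	0.0	1
0	8	503.7	0.0	1
1	8	804.3	0.0	1
2	8	267.5	0.0	1
3	8	733.0	0.0	1
4	8	510.1	0.0	1
5	8	362.0	0.0	1
6	8	333.6	0.0	1
7	8	2053.8	0.0	1
8	8	1101.2	0.0	1
9	8	564.1	0.0	1
10	8	2267.1	0.0	1
11	8	723.6	0.0	1
12	8	453.8	0.0	1
13	8	296.7	0.0	1
14	8	1080.3	0.0	1
15	8	35.7	0.0	1
0	9	1607.7	0.0	1
1	9	79.9	0.0	1
2	9	339.2	0.0	1
3	9	726.2	0.0	1
4	9	303.8	0.0	1
5	9	1583.1	0.0	1
6	9	1357.8	0.0	1
7	9	915.9	0.0	1
8	9	874.9	0.0	1
9	9	956.4	0.0	1
10	9	310.9	0.0	1
11	9	1051.7	0.0	1
12	9	106.5	0.0	1
13	9	126.2	0.0	1
14	9	261.5	0.0	1
15	9	404.6	0.0	1
0	10	2164.6	0.0	1
1	10	92.9	0.0	1
2	10	82.0	0.0	1
3	10	732.9	0.0	1
4	10	172.5	0.0	1
5	10	196.7	0.0	1
6	10	1033.4	0.0	1
7	10	1156.8	0.0	1
8	10	338.8	0.0	1
9	10	1432.2	0.0	1
10	10	374.7	0.0	1
11	10	73.3	0.0	1
12	10	1021.9	0.0	1
13	10	118.5	0.0	1
14	10	258.6	0.0	1
15	10	353.7	0.0	1
0	11	28.1	0.0	1
1	11	417.0	0.0	1
2	11	2418.8	0.0	1
3	11	173.8	0.0	1
4	11	88.8	0.0	1
5	11	1166.1	0.0	1
6	11	3854.5	0.0	1
7	11	448.3	0.0	1
8	11	2057.8	0.0	1
9	11	662.1	0.0	1
10	11	557.8	0.0	1
11	11	510.5	0.0	1
12	11	564.4	0.0	1
13	11	82.6	0.0	1
14	11	870.6	0.0	1
15	11	146.1	0.0	1
0	12	5556.9	0.0	1
1	12	313.2	0.0	1
2	12	92.6	0.0	1
3	12	3031.7	0.0	1
4	12	142.8	0.0	1
5	12	28.7	0.0	1
6	12	645.3	0.0	1
7	12	307.2	0.0	1
8	12	157.0	0.0	1
9	12	5122.7	0.0	1
10	12	197.6	0.0	1
11	12	33.6	0.0	1
12	12	182.0	0.0	1
13	12	3572.2	0.0	1
14	12	162.4	0.0	1
15	12	128.1	0.0	1
0	13	260.1	0.0	1
1	13	2690.7	0.0	1
2	13	54.7	0.0	1
3	13	657.6	0.0	1
4	13	164.0	0.0	1
5	13	226.8	0.0	1
6	13	153.5	0.0	1
7	13	489.0	0.0	1
8	13	521.8	0.0	1
9	13	876.7	0.0	1
10	13	838.4	0.0	1
11	13	6042.0	0.0	1
12	13	288.4	0.0	1
13	13	9.8	0.0	1
14	13	96.1	0.0	1
15	13	73.4	0.0	1
0	14	189.8	0.0	1
1	14	1543.4	0.0	1
2	14	112.9	0.0	1
3	14	70.9	0.0	1
4	14	698.8	0.0	1
5	14	905.5	0.0	1
6	14	219.5	0.0	1
7	14	522.3	0.0	1
8	14	415.2	0.0	1
9	14	299.9	0.0	1
10	14	167.7	0.0	1
11	14	750.9	0.0	1
12	14	9.6	0.0	1
13	14	781.0	0.0	1
14	14	402.7	0.0	1
15	14	4062.7	0.0	1
0	15	398.2	0.0	1
1	15	234.2	0.0	1
2	15	1231.2	0.0	1
3	15	588.7	0.0	1
4	15	311.8	0.0	1
5	15	263.2	0.0	1
6	15	295.1	0.0	1
7	15	73.0	0.0	1
8	15	1409.3	0.0	1
9	15	116.7	0.0	1
10	15	173.8	0.0	1
11	15	594.4	0.0	1
12	15	148.7	0.0	1
13	15	260.6	0.0	1
14	15	2210.2	0.0	1
15	15	140.8	0.0	1
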