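chrom	arm	start	end	excluded
1	1p	1	123400000	0
1	1q	123400001	248956422	0
2	2p	1	93900000	0
2	2q	93900001	242193529	0
3	3p	1	90900000	0
3	3q	90900001	198295559	0
4	4p	1	50000000	0
4	4q	50000001	190214555	0
5	5p	1	48800000	0
5	5q	48800001	181538259	0
6	6p	1	59800000	0
6	6q	59800001	170805979	0
7	7p	1	60100000	0
7	7q	60100001	159345973	0
8	8p	1	45200000	0
8	8q	45200001	145138636	0
9	9p	1	43000000	0
9	9q	43000001	138394717	0
10	10p	1	39800000	0
10	10q	39800001	133797422	0
11	11p	1	53400000	0
11	11q	53400001	135086622	0
12	12p	1	35500000	0
12	12q	35500001	133275309	0
13	13p	1	17700000	1
13	13q	17700001	114364328	0
14	14p	1	17200000	1
14	14q	17200001	107043718	0
15	15p	1	19000000	1
15	15q	19000001	101991189	0
16	16p	1	36800000	0
16	16q	36800001	90338345	0
17	17p	1	25100000	0
17	17q	25100001	83257441	0
18	18p	1	18500000	0
18	18q	18500001	80373285	0
19	19p	1	26200000	0
19	19q	26200001	58617616	0
20	20p	1	28100000	0
20	20q	28100001	64444167	0
21	21p	1	12000000	1
21	21q	12000001	46709983	0
22	22p	1	15000000	1
22	22q	15000001	50818468	0
X	Xp	1	61000000	0
X	Xq	61000001	156040895	0
Y	Yp	1	10400000	0
Y	Yq	10400001	57227415	0
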