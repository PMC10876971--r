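cytoband	chrom	start	end
1p34	1	34600000	46300000
1q32	1	203300000	214100000
2p24	2	12200000	23800000
3q21	3	122000000	129500000
3q26	3	153700000	177300000
6p21	6	30500000	46200000
7p11	7	50300000	58100000
7q31	7	107400000	127100000
8p11	8	36700000	45200000
8q24	8	116700000	145138636
10q22	10	72300000	80300000
10q26	10	119800000	133797422
11q13	11	68700000	77100000
12p12	12	14600000	26300000
12q15	12	62300000	71100000
17q12	17	36000000	40200000
17q21	17	40200000	50200000
19q12	19	28000000	32400000
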