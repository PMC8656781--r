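table	chrom	status	OpenSea	Island	Shelf	Shore
t1	chr1	hypo	786	39	142	179
t1	chr1	hyper	57	636	10	210
t1	chr2	hypo	861	40	137	168
t1	chr2	hyper	36	568	5	154
t1	chr3	hypo	532	17	73	70
t1	chr3	hyper	30	430	15	155
t1	chr4	hypo	442	5	83	85
t1	chr4	hyper	12	462	7	120
t1	chr5	hypo	588	28	91	118
t1	chr5	hyper	62	541	4	116
t1	chr6	hypo	781	13	96	111
t1	chr6	hyper	75	503	17	201
t1	chr7	hypo	728	55	151	195
t1	chr7	hyper	50	533	21	162
t1	chr8	hypo	597	29	93	142
t1	chr8	hyper	26	502	7	164
t1	chr9	hypo	106	13	26	69
t1	chr9	hyper	12	177	5	28
t1	chr10	hypo	506	26	101	121
t1	chr10	hyper	40	573	5	116
t1	chr11	hypo	686	19	84	131
t1	chr11	hyper	41	448	4	147
t1	chr12	hypo	485	18	78	115
t1	chr12	hyper	43	357	20	109
t1	chr13	hypo	517	17	85	97
t1	chr13	hyper	29	372	11	170
t1	chr14	hypo	253	9	39	58
t1	chr14	hyper	13	220	5	74
t1	chr15	hypo	313	9	35	39
t1	chr15	hyper	9	219	4	34
t1	chr16	hypo	267	29	68	121
t1	chr16	hyper	35	295	15	59
t1	chr17	hypo	242	7	75	80
t1	chr17	hyper	27	229	4	46
t1	chr18	hypo	37	14	33	27
t1	chr18	hyper	1	161	4	22
t1	chr19	hypo	262	40	114	119
t1	chr19	hyper	37	524	18	147
t1	chr20	hypo	223	41	88	127
t1	chr20	hyper	2	385	5	85
t1	chr21	hypo	67	4	18	23
t1	chr21	hyper	5	88	0	20
t1	chr22	hypo	63	23	37	49
t1	chr22	hyper	1	98	3	21
t2	chr1	hypo	5	0	0	0
t2	chr1	hyper	0	1	0	2
t2	chr2	hypo	1	0	0	0
t2	chr2	hyper	0	0	0	0
t2	chr3	hypo	6	0	0	0
t2	chr3	hyper	1	1	0	0
t2	chr4	hypo	0	0	0	0
t2	chr4	hyper	0	0	0	0
t2	chr5	hypo	1	0	0	0
t2	chr5	hyper	0	0	0	0
t2	chr6	hypo	5	0	0	0
t2	chr6	hyper	0	0	0	0
t2	chr7	hypo	12	0	0	0
t2	chr7	hyper	0	0	0	0
t2	chr8	hypo	1	0	0	1
t2	chr8	hyper	0	3	0	7
t2	chr9	hypo	1	0	0	0
t2	chr9	hyper	0	0	0	0
t2	chr10	hypo	0	1	3	2
t2	chr10	hyper	0	0	0	0
t2	chr11	hypo	2	0	0	0
t2	chr11	hyper	2	12	0	0
t2	chr12	hypo	0	0	0	0
t2	chr12	hyper	0	0	0	0
t2	chr13	hypo	12	0	3	1
t2	chr13	hyper	0	0	0	0
t2	chr14	hypo	25	1	1	2
t2	chr14	hyper	0	0	0	0
t2	chr15	hypo	1	1	0	1
t2	chr15	hyper	0	5	0	0
t2	chr16	hypo	1	0	0	0
t2	chr16	hyper	0	0	0	1
t2	chr17	hypo	0	0	0	0
t2	chr17	hyper	0	0	0	0
t2	chr17	hypo	0	0	0	0
t2	chr18	hyper	0	0	0	0
t2	chr18	hypo	20	0	0	0
t2	chr19	hyper	0	0	0	0
t2	chr19	hypo	5	0	0	0
t2	chr20	hyper	0	18	0	1
t2	chr20	hypo	0	0	0	0
t2	chr21	hyper	0	0	0	0
t2	chr21	hypo	0	0	0	0
t2	chr22	hyper	1	0	0	0
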