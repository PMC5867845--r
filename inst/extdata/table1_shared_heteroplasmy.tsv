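pair	np	ref	major_allele	minor_allele	sample_id	role	tissue	minor_freq_pct
1	16183	A	A	G	807	mother	buccal	7.32
1	16183	A	A	G	803	child	buccal	6.89
1	16183	A	A	G	M490	mother	blood	2.81
1	16183	A	A	G	M490-C	child	blood	2.46
2	16189	T	T	C	618	mother	buccal	7.74
2	16189	T	T	C	606	child	buccal	11.07
2	16189	T	T	C	M249	mother	blood	2.81
2	16189	T	T	C	M249-C	child	blood	9.92
3	6152	T	T	C	704	mother	buccal	7.23
3	6152	T	T	C	630	child	buccal	16.37
3	6152	T	T	C	M234	mother	blood	5.04
3	6152	T	T	C	M234-C	child	blood	16.48
4	10873	T	T	C	762	mother	buccal	2.53
4	10873	T	T	C	702	child	buccal	6.66
4	10873	T	T	C	M210	mother	blood	NA
4	10873	T	T	C	M210-C	child	blood	5.40
5	1656	A	G	A	729	mother	buccal	2.11
5	1656	A	G	A	684	child	buccal	2.52
5	1656	A	G	A	M213	mother	blood	2.77
5	1656	A	G	A	M213-C	child	blood	2.68
6	3243	A	A	G	1091	mother	buccal	30.72
6	3243	A	G	A	1111	child	buccal	33.10
6	3243	A	A	G	M512	mother	blood	13.13
6	3243	A	G	A	M512-C	child	blood	41.01
6	5539	A	G	A	1091	mother	buccal	41.94
6	5539	A	A	G	1111	child	buccal	24.54
6	5539	A	G	A	M512	mother	blood	23.13
6	5539	A	A	G	M512-C	child	blood	31.26
6	16192	C	T	C	1091	mother	buccal	19.23
6	16192	C	T	C	1111	child	buccal	14.10
6	16192	C	T	C	M512	mother	blood	22.78
6	16192	C	T	C	M512-C	child	blood	17.30
7	16093	T	T	C	1098	mother	buccal	11.53
7	16093	T	C	T	1100	child	buccal	3.45
7	16093	T	T	C	M520	mother	blood	9.12
7	16093	T	C	T	M520-C	child	blood	NA
8	2352	T	C	T	1267	mother	buccal	48.11
8	2352	T	C	T	1160	child	buccal	26.81
8	2352	T	C	T	SC16	mother	blood	47.93
8	2352	T	C	T	SC16-C	child	blood	26.84
9	11635	C	C	T	839	mother	buccal	8.34
9	11635	C	C	T	1189	child	buccal	17.93
9	11635	C	C	T	M494	mother	blood	7.23
9	11635	C	C	T	M494-C	child	blood	19.88
10	15047	G	G	A	632	mother	buccal	21.08
10	15047	G	G	A	696	child	buccal	26.67
10	15047	G	G	A	M236	mother	blood	19.47
10	15047	G	G	A	M236-C	child	blood	28.22
11	5107	C	C	T	531	mother	buccal	9.74
11	5107	C	C	T	572	child	buccal	13.07
11	5107	C	C	T	M-188	mother	blood	8.19
11	5107	C	C	T	M188-C	child	blood	10.05
12	15262	T	T	C	616	mother	buccal	8.36
12	15262	T	T	C	643	child	buccal	15.81
12	15262	T	T	C	M252	mother	blood	7.46
12	15262	T	T	C	M252-C	child	blood	15.49
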