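pair	np	ref	sample_id	role	tissue	major_allele	major_fwd	major_rev	major_freq_pct	minor_allele	minor_fwd	minor_rev	minor_freq_pct	gene	synonymous	aa_change
1	2746	T	693	mother	buccal	T	2920	6014	79.67	C	655	1600	20.11	16S		
1	2746	T	677	child	buccal	T	4838	14038	99.64	C	1	9	0.053			
1	2746	T	M207	mother	blood	T	14187	14328	80.3	C	3440	3528	19.62	16S		
1	2746	T	M207-C	child	blood	T	24044	24176	99.88	C	6	12	0.037			
2	16320	C	406	mother	buccal	C	4918	3843	72.33	T	1866	1474	27.57	CR		
2	16320	C	444	child	buccal	C	17616	13273	99.92	T	9	7	0.052			
2	16320	C	M137	mother	blood	C	5412	4619	94.9	T	288	248	5.07	CR		
2	16320	C	M137-C	child	blood	C	4232	3670	99.92	T	2	1	0.038			
3	9179	T	1134	mother	buccal	T	3063	5076	85.02	C	538	892	14.93	ATP6	N	Val to Ala
3	9179	T	1099	child	buccal	T	6651	8730	99.82	C	8	7	0.097			
3	9179	T	M502G	mother	blood	T	16583	20269	87.14	C	2468	2934	12.77	ATP6	N	Val to Ala
3	9179	T	M501	child	blood	T	38769	44060	99.81	C	32	24	0.067			
4	14040	G	659	mother	buccal	G	5770	4227	92.01	A	474	381	7.86	ND5	Y	Gln
4	14040	G	722	child	buccal	G	20789	16141	99.86	A	8	12	0.054			
4	14040	G	M242	mother	blood	G	13200	12992	94.07	A	831	811	5.89	ND5	Y	Gln
4	14040	G	M242-C	child	blood	G	10355	10087	99.88	A	5	5	0.049			
5	14461	T	411	mother	buccal	T	7078	7720	97.04	C	205	233	2.87	ND6	Y	Thr
5	14461	T	401	child	buccal	T	16084	15992	99.78	C	35	18	0.165			
5	14461	T	M132	mother	blood	T	8475	8875	97.54	C	193	237	2.41	ND6	Y	Thr
5	14461	T	M132-C	child	blood	T	5854	6622	99.92	C	8	1	0.072			
6	11825	G	711	mother	buccal	G	1622	2662	93.41	A	116	184	6.54	ND4	N	Ala to Thr
6	11825	G	737	child	buccal	G	8943	15813	99.8	A	8	3	0.044			
6	11825	G	M203	mother	blood	G	4728	5871	97.1	A	133	167	2.74	ND4	N	Ala to Thr
6	11825	G	M203-C	child	blood	G	14625	18730	99.88	A	6	5	0.033			
6	12375	T	711	mother	buccal	T	1713	1597	99.67	C	1	9	0.301			
6	12375	T	737	child	buccal	T	6368	6238	72.03	C	2770	2099	27.82	ND5	Y	Thr
6	12375	T	M203	mother	blood	T	4588	4190	99.66	C	13	12	0.284			
6	12375	T	M203-C	child	blood	T	10455	10132	76	C	3481	3008	23.95	ND5	Y	Thr
7	13790	A	729	mother	buccal	A	2539	943	99.63	G	1	1	0.057			
7	13790	A	684	child	buccal	A	5501	2427	88.46	G	650	356	11.22	ND5	N	Tyr to Cys
7	13790	A	M213	mother	blood	A	10487	7516	99.46	G	4	25	0.160			
7	13790	A	M213-C	child	blood	A	5900	4359	88.44	G	705	583	11.1	ND5	N	Tyr to Cys
8	200	A	1098	mother	buccal	G	1350	3677	96.58	A	31	139	3.26	CR		
8	200	A	1100	child	buccal	G	1148	3998	98.79	A	5	54	1.13			
8	200	A	M520	mother	blood	G	821	1294	97.6	A	17	32	2.26	CR		
8	200	A	M520-C	child	blood	G	5713	9174	99.59	A	14	41	0.368			
9	4191	A	1122	mother	buccal	A	8781	10930	99.36	T	2	27	0.146			
9	4191	A	1119	child	buccal	A	4452	5729	95.5	T	202	243	4.17	ND1	Y	Pro
9	4191	A	M500	mother	blood	A	5699	6469	99.37	T	3	25	0.229			
9	4191	A	M500-C	child	blood	A	12277	14284	94.96	T	612	695	4.67	ND1	Y	Pro
10	16170	A	1267	mother	buccal	A	17593	21027	94.49	G	1060	1174	5.46	CR		
10	16170	A	1160	child	buccal	A	15700	21013	99.95	G	4	5	0.025			
10	16170	A	SC16	mother	blood	A	8155	10691	96.19	G	332	413	3.8	CR		
10	16170	A	SC16-C	child	blood	A	10154	13352	99.97	G	1	2	0.013			
11	9196	G	839	mother	buccal	G	6061	10535	97.36	A	172	265	2.56	ATP6	N	Asp to Asn
11	9196	G	1189	child	buccal	G	4644	7284	99.81	A	0	6	0.050			
11	9196	G	M494	mother	blood	G	14294	16248	97.83	A	306	362	2.13	ATP6	N	Asp to Asn
11	9196	G	M494-C	child	blood	G	10236	11242	99.95	A	0	3	0.014			
11	3183	T	839	mother	buccal	T	12953	24373	99.67	C	26	53	0.211			
11	3183	T	1189	child	buccal	T	12210	26317	96.49	C	412	937	3.37	16S		
11	3183	T	M494	mother	blood	T	36453	46743	99.85	C	40	63	0.124			
11	3183	T	M494-C	child	blood	T	30655	39617	96.78	C	970	1333	3.17	16S		
11	15948	A	839	mother	buccal	A	15680	15099	99.87	G	13	13	0.084			
11	15948	A	1189	child	buccal	A	21533	19721	95.35	G	1039	902	4.48	tRNA-Thr		
11	15948	A	M494	mother	blood	A	24430	24443	99.95	G	7	7	0.029			
11	15948	A	M494-C	child	blood	A	30887	30673	96.64	G	1074	1041	3.32	tRNA-Thr		
12	11288	C	740	mother	buccal	C	18404	14646	99.97	T	2	1	0.009			
12	11288	C	718	child	buccal	C	68908	55901	95.69	T	3140	2418	4.26	ND4	Y	Leu
12	11288	C	M211	mother	blood	C	38204	36874	99.95	T	8	17	0.033			
12	11288	C	M211-C	child	blood	C	46511	43582	96.58	T	1651	1523	3.4	ND4	Y	Leu
13	596	T	739	mother	buccal	T	3088	856	84.7	C	552	155	15.18	tRNA-Phe		
13	596	T	725	child	buccal	T	9324	2728	99.37	C	3	13	0.132			
13	596	T	M200	mother	blood	T	1745	1125	95.15	C	93	52	4.8	tRNA-Phe		
13	596	T	M200-C	child	blood	T	5520	3270	99.82	C	8	4	0.136			
14	926	A	605	mother	buccal	A	7528	4119	96.48	G	275	147	3.49	12S		
14	926	A	619	child	buccal	A	23698	18664	99.95	G	7	5	0.028			
14	926	A	M240	mother	blood	A	3882	3469	96.29	G	149	131	3.66	12S		
14	926	A	M240-C	child	blood	A	4476	4483	99.92	G	2	2	0.043			
15	14573	A	632	mother	buccal	A	3406	2340	70.79	G	1390	966	29.02	ND6	N	Val to Ala
15	14573	A	696	child	buccal	A	5484	4707	99.73	G	1	4	0.049			
15	14573	A	M236	mother	blood	A	7546	6525	77.51	G	2240	1839	22.47	ND6	N	Val to Ala
15	14573	A	M236-C	child	blood	A	8151	7438	99.95	G	3	1	0.026			
15	214	A	632	mother	buccal	A	886	2300	99.75	G	3	4	0.219			
15	214	A	696	child	buccal	A	1739	2434	91.43	G	156	230	8.45	CR		
15	214	A	M236	mother	blood	A	3777	4526	99.99	G	0	1	0.012			
15	214	A	M236-C	child	blood	A	3426	4146	96.87	G	119	124	3.1	CR		
16	16240	A	531	mother	buccal	A	1424	1744	99.75	G	3	2	0.157			
16	16240	A	572	child	buccal	A	24590	25415	90.81	G	2527	2455	9.04	CR		
16	16240	A	M-188	mother	blood	A	16073	16853	99.88	G	4	9	0.039			
16	16240	A	M188-C	child	blood	A	13732	14444	94.28	G	823	855	5.61	CR		
17	9983	A	616	mother	buccal	A	2944	7014	99.83	G	5	12	0.170			
17	9983	A	643	child	buccal	A	11623	20991	97.33	G	314	547	2.56	CO3	Y	Trp
17	9983	A	M252	mother	blood	A	11354	14962	99.83	G	18	22	0.152			
17	9983	A	M252-C	child	blood	A	17123	22272	97.91	G	346	468	2.02	CO3	Y	Trp
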