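set	ssr_id	type	motif	lg	position_cm	n_alleles	size_range	d_min_bp	pic	ne1p	primer_pmol
1	PVAAG-3163/4	gSSR	(ACA)29	5b	63.5	19	211-293	16	0.925	0.248	1
1	PVGA-1143/4	gSSR	(GA)7-(GA)8	5a	29.3	20	156-195		0.926	0.246	1
2	PVCAG-2397/8	gSSR	(CAG)12	3b	36.3	9	161-189	73	0.822	0.484	2
2	PVCAG-2517/8	gSSR	(GCT)8	9a	6.9	15	213-234		0.879	0.362	2
3	PVCAG-2147/8	gSSR	(CAG)7	6b	150.5	12	285-306	68	0.836	0.454	1
3	SWW-1394	eSSR	(GGT)n	7a,VIIa	60.4	8	194-217		0.651	0.709	0.5
4	SWW-463	eSSR	(TG)n	9a	58.3	7	253-273	108	0.762	0.58	0.5
4	PVAAG-3017/8	gSSR	(AAG)11	6b	58.8	8	132-145		0.787	0.539	0.5
5	PVAAG-3091/2	gSSR	(TTC)13	9a	79.5	13	304-346	71	0.867	0.39	1
5	PVAAG-3245/6	gSSR	(TTC)9	2a	91.4	19	102-233		0.929	0.237	0.25
6	NFSG-112	gSSR	(GA)n	8b,VIIIb	48	4	189-195	22	0.65	0.472	0.5
6	NFSG-036	gSSR	(GA)n	4a,IVa	0	17	120-167		0.91	0.289	0.5
7	SWW-573	eSSR	(CAG)n	2b	39.5	11	229-247	60	0.767	0.561	1
7	PVCAG-2473/4	gSSR	(GCA)12	3a	60.8	13	138-169		0.896	0.325	4
8	PVAAG-2895/6	gSSR	(GAA)10	5b	118	23	310-413	82	0.936	0.215	4
8	PVCAG-2527/8	gSSR	(GCT)9	4b	60.8	12	206-228		0.867	0.392	4
9	NFSG-200	gSSR	(GA)n	9b,IXb	76.4	15	107-146	19	0.884	0.35	1
9	NFSG-219	gSSR	(GA)n	8b,VIIIb	26.6	19	165-199		0.928	0.243	1
10	SWW-387	eSSR	(CT)n	9b	46.5	5	154-159	44	0.622	0.49	2
10	PVGA-1663/4	gSSR	(AG)13	9b	34.1	17	203-230		0.89	0.332	2
11	PVAAG-3051/2	gSSR	(GAA)29	7a	31.8	15	185-254	10	0.851	0.418	1
11	PVCAG-2209/10	gSSR	(GC)8	4a	13.4	9	264-274		0.839	0.452	1
12	PVCAG-2207/8	gSSR	(CTG)5	2b	40.3	7	221-238	29	0.677	0.685	0.125
12	PVCAG-2289/90	gSSR	(TGC)5	4b	61	16	157-192		0.886	0.343	0.25
13	PVCAG-2187/8	gSSR	(GCA)7	8b	69.4	13	152-179	99	0.859	0.404	1
13	PVGA-1549/50	gSSR	(GAA)6	1b	83.5	11	278-331		0.85	0.428	1
14	SWW-2662	eSSR	(AGG)n	2b,IIb	73.5	10	178-197	43	0.774	0.555	1
14	5211_B07	eSSR	(AGC)8	2a	17.2	7	240-253		0.799	0.525	1
15	PVGA-1357/8	gSSR	(AC)7-(GA)22	5a	59.5	22	229-337	3	0.938	0.211	1
15	PVGA-1301/2	gSSR	(TC)22	9b	50.5	17	163-226		0.914	0.279	1.5
16	PVGA-1243/4	gSSR	(TC)23	5b	69.3	25	280-317	62	0.945	0.191	2
16	PVCAG-2297/8	gSSR	(CAG)6	3a	66.6	15	177-218		0.866	0.386	0.5
17	PVAAG-3311/2	gSSR	(CTT)28	2a	29.6	12	140-170	66	0.883	0.353	0.5
17	PVGA-1813/4	gSSR	(GA)7	5a	72.2	18	236-276		0.915	0.277	1
18	NFSG-035	gSSR	(GA)n	3a,IIIa	129.2	13	117-151	52	0.897	0.325	1
18	SWW-125	gSSR	(GA)n	2b,IIb	45.5	5	203-220		0.629	0.487	1
19	PVCA-893/4	gSSR	(AC)19	3b	65.3	9	297-336	81	0.78	0.546	1
19	SWW-1615	eSSR	(GGC)n	1a,Ia	109.8	17	185-216		0.873	0.368	1
20	SWW-1622	eSSR	(GCG)n	2b,IIb	56.3	6	233-246	15	0.77	0.576	1
20	SWW-1889	eSSR	(GCT)n	6b,VIb	72	4	211-218		0.624	0.484	1
21	PVCA-415/6	gSSR	(TG)16	6a	68.1	20	137-172	5	0.93	0.236	1
21	SWW-1643	eSSR	(GA)n	3b	136	12	177-207		0.881	0.361	2
22	PVCA-979/80	gSSR	(GT)30	8a	50.2	8	283-310	60	0.678	0.679	2
22	SWW-2376	eSSR	(CTG)n	5b,Vb	111.5	9	204-223		0.655	0.703	2
23	PVCAG-2269/70	gSSR	(CAG)8	4b	0	17	209-262	6	0.906	0.298	0.5
23	PVCAG-2361/2	gSSR	(AGC)8	1b	25.9	8	268-277		0.705	0.648	1
24	PVCAG-2279/80	gSSR	(GCT)8	5a	11.7	11	236-248	14	0.83	0.46	0.25
24	PVGA-1963/4	gSSR	(GA)9-(AG)6	5b	66.5	17	191-222		0.908	0.294	2
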