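SNP	CHR	BP	GENE	A1	A2	EAF	BETA	SE	P
rs3219104	1	226562621	PARP1	C	A	0.83	-0.033	0.022	0.13
rs10936600	3	169514585	TERC	T	A	0.24	0.006	0.018	0.74
rs4691895	4	164048199	NAF1	C	G	0.78	-0.022	0.019	0.24
rs7705526	5	1285974	TERT	A	C	0.33	0.008	0.017	0.66
rs2853677	5	1287194	TERT	A	G	0.59	-0.007	0.016	0.65
rs59294613	7	124554267	POT1	A	C	0.29	-0.007	0.017	0.69
rs9419958	10	105675946	STN1	C	T	0.86	0.005	0.023	0.84
rs228595	11	108105593	ATM	A	G	0.42	0.004	0.016	0.81
rs2302588	14	73404752	DCAF4	C	G	0.10	0.024	0.026	0.36
rs7194734	16	82199980	STMN3	T	C	0.78	-0.024	0.019	0.19
rs8105767	19	22215441	ZNF208	G	A	0.30	0.007	0.017	0.67
rs75691080	20	62269750	STMN3	T	C	0.09	-0.026	0.029	0.37
rs34978822	20	62291599	RTEL1	G	C	0.02	0.104	0.053	0.05
rs73624724	20	62436398	RTEL1	C	T	0.13	-0.028	0.023	0.22
rs55749605	3	101232093	SENP7	A	C	0.58	-0.009	0.016	0.56
rs13137667	4	71774347	MOB1B	C	T	0.96	0.036	0.049	0.46
rs34991172	6	25480328	CARMIL	G	T	0.07	0.031	0.028	0.28
rs2736176	6	31587561	PRRC2A	C	G	0.31	-0.006	0.017	0.73
rs3785074	16	69406986	TERF2	G	A	0.26	0.004	0.017	0.83
rs62053580	16	74680074	RFWD3	G	A	0.17	-0.050	0.021	0.02
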