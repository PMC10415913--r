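rank_prev	rule	confidence	support	lift	avg_wesd	relative_score	rank_after
1	STAT3+ -> MAPK3+	0.009	0.003461538	0.0195	0.00339	0.3596	2
2	TP53- -> MAPK3+	0.008888889	0.003076923	0.01925926	0.00408	0.3547	6
3	MAPK3+, TP53- -> STAT3+	0.00875	0.002692308	0.02275	0.00543	0.346	15
4	STAT3+, TP53- -> MAPK3+	0.01	0.002692308	0.02166667	0.003735	0.36	1
5	ESR1+ -> MAPK3+	0.008333333	0.001923077	0.01805556	0.00357	0.3565	4
6	JUN+, STAT3+ -> MAPK3+	0.008571429	0.002307692	0.01857143	0.00388	0.355	5
7	JUN+, FYN+ -> MAPK3+	0.01	0.002307692	0.02166667	0.008	0.3354	22
8	STAT3+, FYN+ -> MAPK3+	0.01	0.002692308	0.02166667	0.00751	0.3384	19
9	JUN+, TP53- -> MAPK3+	0.008571429	0.002307692	0.01857143	0.004225	0.3525	7
10	JUN+, STAT3+, TP53 -> MAPK3+	0.01	0.001923077	0.02166667	0.003946667	0.3588	3
11	FYN+, TP53 -> MAPK3+	0.01	0.002307692	0.02166667	0.007855	0.3361	21
12	JUN+, AR+ -> MAPK3+	0.01	0.001923077	0.02166667	0.00567	0.3474	14
13	JUN+, AR+ -> TP53-	0.01	0.001923077	0.02888889	0.0072	0.3399	18
14	TP53-, AR+ -> JUN+	0.01	0.001923077	0.026	0.00541	0.3494	13
15	JUN+, AR+ -> MAPK3+, TP53-	0.01	0.001923077	0.0325	0.006435	0.3444	17
16	MAPK3+, JUN+, AR+ -> TP53-	0.01	0.001923077	0.02888889	0.00616	0.3454	16
17	TP53-, AR+ -> MAPK3+, JUN+	0.01	0.001923077	0.0325	0.0054675	0.3496	12
18	MAPK3+, TP53-, AR+ -> JUN+	0.01	0.001923077	0.026	0.005063333	0.3514	9
19	JUN+, TP53-, AR+ -> MAPK3+	0.01	0.001923077	0.02166667	0.00514	0.351	11
20	GRB2 -> STAT3-	0.01	0.002692308	0.02888889	0.01145	0.324	23
21	FYN -> TP53+	0.01	0.003076923	0.026	0.01186	0.3228	24
22	ESR1-, FYN -> TP53+	0.01	0.002307692	0.026	0.00783	0.337	20
23	ESR1-, MAPK3 -> STAT3-	0.01	0.001923077	0.02888889	0.005065	0.3516	8
24	STAT3-, MAPK3 -> ESR1-	0.01	0.001923077	0.02888889	0.005155	0.3511	10
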