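rule_id	rule	accuracy	specificity	sensitivity	auc	std_err_rate
1	STAT3- -> GRB2-	0.8423	0.8384	0.8769	0.878	0.01216261
2	STAT3-, MAPK3- -> GRB2-	0.8346	0.7692	1.00	0.888	0.01986145
3	MAPK3-, GRB2- -> STAT3-	0.8846	0.7692	1.00	0.888	0.01216261
4	GRB2- -> STAT3-	0.8115	0.8538	0.7692	0.90	0.01813094
5	ESR1- -> MAPK3-	0.7653	0.7692	0.7615	0.815	0.02564103
6	STAT3- -> MAPK3-	0.8423	0.7923	0.8846	0.915	0.02183255
7	STAT3-, GRB2- -> MAPK3-	0.8461	0.823	0.8692	0.902	0.021832557
8	GRB2- -> MAPK3-	0.7884	0.7461	0.8307	0.817	0.02689253
9	ESR1- -> GRB2-	0.8307	0.7769	0.8846	0.826	0.03715738
10	JUN- -> GRB2-	0.75	0.6538	0.8769	0.777	0.0373779
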