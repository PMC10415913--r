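rule_id	rule	accuracy	specificity	sensitivity	auc	std_err_rate
1	STAT3-, MAPK3- -> GRB2-	0.8461	0.8538	0.8384	0.902	0.02183255
2	STAT3- -> GRB2-	0.8076	0.8461	0.7692	0.897	0.02432521
3	MAPK3-, GRB2- -> STAT3-	0.8461	0.8538	0.8384	0.903	0.01621681
4	GRB2- -> STAT3-	0.8115	0.8538	0.7692	0.90	0.01813094
5	ESR1- -> MAPK3-	0.7692	0.7923	0.7769	0.816	0.02564103
6	STAT3- -> GRB2-	0.8077	0.8462	0.7692	0.897	0.02432521
7	STAT3- -> MAPK3-	0.8423	0.7769	0.9077	0.915	0.02183255
8	GRB2- -> MAPK3-	0.8462	0.7692	0.9230	0.817	0.02689253
9	ESR1-, GRB2-	0.8346	0.7615	0.9077	0.826	0.03715738
10	FYN+ -> TP53-	0.7538	0.6846	0.8230	0.714	0.0373779
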