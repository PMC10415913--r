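rule_id	rule	accuracy	specificity	sensitivity	auc	std_err_rate
1	STAT3+, TP53- -> MAPK3+	0.8538	0.8538	0.8384	0.926	0.04054202
2	STAT3+ -> MAPK3+	0.8461	0.7692	0.9230	0.918	0.01813094
3	JUN+, STAT3+, TP53- -> MAPK3+	0.8923	0.8923	0.8923	0.967	0.03243362
4	ESR1+ -> MAPK3+	0.8076	0.7692	0.7615	0.83	0.02432521
5	JUN+, STAT3+ -> MAPK3+	0.923	0.90	0.8769	0.956	0.02432521
6	TP53- -> MAPK3+	0.7384	0.8538	0.8384	0.771	0.03972291
7	JUN+, TP53- -> MAPK3+	0.8346	0.9538	0.7153	0.877	0.05063697
8	ESR1-, MAPK3+ -> STAT3+	0.8461	0.8384	0.8538	0.942	0.02689253
9	MAPK3+, TP53-, AR+ -> JUN+	0.9192	0.8230	0.8230	0.956	0.03268602
10	STAT3+, MAPK3+ -> ESR1-	0.8461	0.8384	0.8538	0.942	0.02689253
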