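# Published cumulative rule-out counts for the 115-patient development cohort.
# cutoff k: number of patients with score <= k, by high-risk-lesion status.
# gbs_* columns: Glasgow-Blatchford score, all patients (totals 35 / 80).
# algo_* columns: combined GBS + nasogastric-aspirate score; at cutoffs < 23
# these count only non-bloody patients (totals 11 / 69), since every
# bloody-aspirate patient scores 23.
cutoff	gbs_cum_with	gbs_cum_without	algo_cum_with	algo_cum_without
0	0	3	0	3
1	1	4	0	4
2	2	6	0	6
3	3	12	0	11
4	3	13	0	12
5	3	13	0	12
6	3	19	0	16
7	4	26	0	21
8	4	28	0	23
9	6	33	0	27
10	10	42	1	36
11	17	52	2	44
12	23	62	3	53
13	26	69	6	59
14	27	72	7	62
15	32	75	10	64
16	34	79	11	68
17	35	80	11	69
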