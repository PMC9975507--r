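line_id	condition	donor_age	DNA_damage	Telomere_attrition	Histone_modification	SA_bGal	SASP	Cell_cycle_arrest	Morphology	LMNB1	n_markers_assessed
Young 1	young	2	0	0	0	0	0	0	0	0	8
Young 2	young	2	0	0	0	0	0	0	0	0	8
Young 3	young	3	0	0	0	0	0	0	0	0	8
Young 4	young	3	0	0	0	0	0	0	0	0	8
Young 5	young	9	0	0	0	0	0	0	0	0	8
Midage 1	midage	34	0	0	0	0	1	0	0	1	8
Midage 2	midage	37	0	0	0	0	0	0	0	0	8
Midage 3	midage	48	0	0	0	1	0	0	0	1	8
Old 1	old	78	0	0	0	1	1	0	0	1	8
Old 2	old	80	0	0	1	1	1	0	0	1	8
Old 3	old	82	0	0	0	1	1	0	0	1	8
Old 4	old	92	1	0	1	1	1	1	1	1	8
Old 5	old	96	1	0	1	1	0	1	1	1	8
Old 6	old	96	0	1	1	1	1	0	0	0	8
Repl Y1	replicative	NA	1	1	0	1	1	1	1	1	8
Repl Y2	replicative	NA	1	1	1	1	1	0	1	1	8
Repl M1	replicative	NA	1	0	1	1	1	1	1	1	8
Repl M2	replicative	NA	1	1	1	1	1	0	1	1	8
Repl O1	replicative	NA	1	0	1	1	1	1	1	1	8
Repl O2	replicative	NA	1	1	1	1	1	1	1	1	8
Young 1 prog	artificial	2	0	0	0	1	1	1	1	1	8
Young 4 prog	artificial	3	1	1	0	1	1	1	1	1	8
Young 5 prog	artificial	9	1	1	0	1	1	1	1	1	8
HGPS 1	HGPS	2	1	0	1	1	1	0	1	1	8
HGPS 2	HGPS	2	1	0	1	1	1	0	1	1	8
WS 1	WS	30	1	0	0	1	0	1	1	1	8
WS 2	WS	37	1	0	0	1	0	1	1	0	8
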