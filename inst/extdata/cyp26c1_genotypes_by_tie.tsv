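cohort	tie_class	hom_ref	het	hom_alt
Reporting Herd 1	one_side	95	50	0
Reporting Herd 1	both_sides	2	5	2
Reporting Herd 1	none	91	0	0
Reporting Herd 2	one_side	114	35	0
Reporting Herd 2	both_sides	4	5	1
Reporting Herd 2	none	239	0	0
Other	one_side	13	20	0
Other	both_sides	48	37	2
Other	none	18	0	0
Other	is_founder	0	1	0
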