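chrom	pos	ref	alt	qual	consequence	gene	impact_label	impact_score
7	15413	C	T	100	intergenic	NA	none	NA
26	10588403	T	A	100	intronic	STAMBPL1	none	NA
26	10616433	C	T	100	downstream	STAMBPL1	none	NA
26	10713132	G	A	100	downstream	FAS	none	NA
26	10794674	G	A	100	intergenic	NA	none	NA
26	10982292	TGAGAGAGGAT	TGAGAGGAT	100	intronic	LIPA	none	NA
26	14404993	T	C	100	missense	CYP26C1	deleterious	0
26	15898152	C	T	100	upstream	TBC1D12	none	NA
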