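chrom	pos	ref	alt	breed	n_samples	n_het	n_hom_alt
7	15413	C	T	Hereford	400	0	0
7	15413	C	T	Angus	400	0	0
26	10588403	T	A	Hereford	400	0	0
26	10588403	T	A	Angus	400	0	0
26	10616433	C	T	Hereford	400	0	0
26	10616433	C	T	Angus	400	0	0
26	10713132	G	A	Romagnola	340	2	0
26	10713132	G	A	Simmental	339	2	0
26	10713132	G	A	Original Braunvieh	339	2	0
26	10794674	G	A	Romagnola	361	3	0
26	10794674	G	A	Simmental	361	2	1
26	10794674	G	A	Original Braunvieh	361	2	0
26	10982292	TGAGAGAGGAT	TGAGAGGAT	Hereford	400	0	0
26	10982292	TGAGAGAGGAT	TGAGAGGAT	Angus	400	0	0
26	14404993	T	C	Hereford	400	0	0
26	14404993	T	C	Angus	400	0	0
26	15898152	C	T	Hereford	400	0	0
26	15898152	C	T	Angus	400	0	0
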