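source	n_animals
WGS for this project	20
Hereford cattle genotyped for this project	762
Other WGS variant data	101
1000 bulls and breed association WGS	1705
Sequence Read Archive	783
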