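partition	clade	members	support	min_terminal_branch	pair_identity	pair_overlap	expected_assessment	expected_action
21904	A	Urechis caupo;Lottia gigantea	99	0.05	0.70	150	potential paralog	partition excluded
21904	B	Myzostoma cirriferum;Pomatoceros lamarckii;Crassostrea gigas	98	0.05	0.68	150	potential paralog	partition excluded
22375	A	Lanice conchilega;Owenia fusiformis	100	0	1	60	contamination	sequences excluded
22431	A	Urechis caupo;Capitella teleta;Arenicola marina	98	0.04	0.72	150	no paralog	none
22433	A	Scoloplos armiger;Sthenelais boa;Eurythoe complanata	100	0.08	0.66	150	potential paralog	sequences excluded
22539	A	Lottia gigantea;Crassostrea gigas;Owenia fusiformis;Terebratalia transversa	100	0.04	0.64	150	no paralog	none
22539	A+B	Urechis caupo;Capitella teleta;Lottia gigantea;Crassostrea gigas;Owenia fusiformis;Terebratalia transversa	96	0.04	0.62	150	no paralog	none
22606	A	Owenia fusiformis;Cerebratulus lacteus	100	0.06	0.70	150	potential paralog	sequences excluded
22636	A	Myzostoma seymourcollegiorum;Alvinella pompejana	98	0.05	0.68	150	no paralog	none
22680	A	Pomatoceros lamarckii;Alvinella pompejana	99	0.03	0.74	150	potential paralog	sequences excluded
22820	A	Lanice conchilega;Owenia fusiformis	100	0	1	80	contamination	sequences excluded
22938	A	Bugula neritina;Crassostrea gigas	98	0.09	0.66	150	no paralog	none
23018	A	Cerebratulus lacteus;Terebratalia transversa	98	0.07	0.72	150	no paralog	none
23291	A	Lanice conchilega;Owenia fusiformis	100	0	1	70	contamination	sequences excluded
23636	A	Hirudo medicinalis;Alvinella pompejana	99	0.1	0.60	150	potential paralog	sequences excluded
23680	A	Glycera tridactyla;Typosyllis pigmentata	100	0	1	90	contamination	sequences excluded
23729	A	Platynereis dumerilii;Eulalia clavigera	96	0.06	0.70	150	no paralog	none
23816	A	Malacoceros fuliginosus;Capitella teleta	96	0.03	0.68	150	potential paralog	partition excluded
23816	B	Ridgeia piscesae;Crassostrea gigas	100	0.03	0.66	150	potential paralog	partition excluded
24126	A	Lottia gigantea;Themiste lageniformis	97	0.05	0.64	150	potential paralog	partition excluded
RPL13a	A	Lanice conchilega;Owenia fusiformis	100	0	1	120	contamination	sequences excluded
RPL15	A	Lanice conchilega;Owenia fusiformis	100	0	1	110	contamination	sequences excluded
RPL24	A	Lanice conchilega;Eisenia fetida	96	0.04	0.70	150	potential paralog	sequences excluded
RPS15	A	Lanice conchilega;Owenia fusiformis	100	0	1	90	contamination	sequences excluded
RPS24	A	Lanice conchilega;Owenia fusiformis	100	0	1	70	contamination	sequences excluded
RPS6	A	Lanice conchilega;Owenia fusiformis	100	0	1	100	contamination	sequences excluded
RPSA	A	Lanice conchilega;Owenia fusiformis	100	0	1	130	contamination	sequences excluded
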