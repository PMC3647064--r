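partition	group	taxon	label	evalue
21904	A	Urechis caupo	Rho GDP dissociation inhibitor beta	1e-62
21904	A	Lottia gigantea	Rho GDP dissociation inhibitor beta	1e-62
21904	B	Myzostoma cirriferum	Rho GDP dissociation inhibitor alpha	1e-33
21904	B	Pomatoceros lamarckii	Rho GDP dissociation inhibitor alpha	1e-60
21904	B	Crassostrea gigas	Rho GDP dissociation inhibitor alpha	1e-63
21904	PT	Capitella teleta	Rho GDP dissociation inhibitor alpha	1e-63
21904	PT	Helobdella robusta	Rho GDP dissociation inhibitor beta	1e-64
22431	A	Urechis caupo	NSA2 ribosome biogenesis homolog	1e-148
22431	A	Capitella teleta	NSA2 ribosome biogenesis homolog	1e-144
22431	A	Arenicola marina	NSA2 ribosome biogenesis homolog	1e-71
22431	PT	Helobdella robusta	NSA2 ribosome biogenesis homolog	1e-141
22431	PT	Lottia gigantea	NSA2 ribosome biogenesis homolog	1e-151
22433	A	Scoloplos armiger	Proteasome subunit alpha2 (PSMA2)	1e-73
22433	A	Sthenelais boa	Proteasome subunit alpha2 (PSMA2)	1e-98
22433	A	Eurythoe complanata	Proteasome subunit alpha2 (PSMA2)	1e-63
22433	PT	Helobdella robusta	Proteasome subunit alpha8 (PSMA8)	1e-135
22433	PT	Lottia gigantea	Proteasome subunit alpha8 (PSMA8)	1e-128
22433	PT	Capitella teleta	Proteasome subunit alpha8 (PSMA8)	1e-130
22539	A	Lottia gigantea	Succinate dehydrogenase complex subunit D	1e-16
22539	A	Crassostrea gigas	Succinate dehydrogenase complex subunit D	1e-17
22539	A	Owenia fusiformis	Succinate dehydrogenase complex subunit D	1e-20
22539	A	Terebratalia transversa	Succinate dehydrogenase complex subunit D	1e-19
22539	A+B	Urechis caupo	Succinate dehydrogenase complex subunit D	1e-13
22539	A+B	Capitella teleta	Succinate dehydrogenase complex subunit D	1e-22
22539	PT	Helobdella robusta	Succinate dehydrogenase complex subunit D	1e-19
22606	A	Owenia fusiformis	Centrin, EF-hand protein 3 (CETN3)	1e-57
22606	A	Cerebratulus lacteus	Centrin, EF-hand protein 3 (CETN3)	1e-56
22606	PT	Capitella teleta	Centrin, EF-hand protein 2 (CETN2)	1e-104
22606	PT	Helobdella robusta	Centrin, EF-hand protein 2 (CETN2)	1e-92
22606	PT	Lottia gigantea	Centrin, EF-hand protein 2 (CETN2)	1e-91
22636	A	Myzostoma seymourcollegiorum	Eukaryotic translation initiation factor 5A2	1e-47
22636	A	Alvinella pompejana	Eukaryotic translation initiation factor 5A2	1e-57
22636	PT	Capitella teleta	Eukaryotic translation initiation factor 5A2	1e-52
22636	PT	Helobdella robusta	Eukaryotic translation initiation factor 5A2	1e-56
22636	PT	Lottia gigantea	Eukaryotic translation initiation factor 5A2	1e-61
22680	A	Pomatoceros lamarckii	heat shock 70 kDa protein 1A	1e-166
22680	A	Alvinella pompejana	heat shock 70 kDa protein 1A	1e-32
22680	PT	Capitella teleta	heat shock 70 kDa protein 8	0
22680	PT	Helobdella robusta	heat shock 70 kDa protein 8	0
22680	PT	Lottia gigantea	heat shock 70 kDa protein 8	0
22938	A	Bugula neritina	NADH dehydrogenase (ubiquinone) 1 alpha subcomplex subunit 13	1e-18
22938	A	Crassostrea gigas	NADH dehydrogenase (ubiquinone) 1 alpha subcomplex subunit 13	1e-26
22938	PT	Capitella teleta	NADH dehydrogenase (ubiquinone) 1 alpha subcomplex subunit 13	1e-20
22938	PT	Helobdella robusta	NADH dehydrogenase (ubiquinone) 1 alpha subcomplex subunit 13	1e-29
22938	PT	Lottia gigantea	NADH dehydrogenase (ubiquinone) 1 alpha subcomplex subunit 13	1e-18
23018	A	Cerebratulus lacteus	proliferating cell nuclear antigen (PCNA)	1e-92
23018	A	Terebratalia transversa	proliferating cell nuclear antigen (PCNA)	1e-119
23018	PT	Capitella teleta	proliferating cell nuclear antigen (PCNA)	1e-136
23018	PT	Helobdella robusta	proliferating cell nuclear antigen (PCNA)	1e-145
23018	PT	Lottia gigantea	proliferating cell nuclear antigen (PCNA)	1e-139
23636	A	Hirudo medicinalis	NADH dehydrogenase (ubiquinone) 1 alpha subcomplex assembly factor 2	1e-9
23636	A	Alvinella pompejana	NADH dehydrogenase (ubiquinone) 1 alpha subcomplex assembly factor 2	0.043
23636	PT	Capitella teleta	NADH dehydrogenase (ubiquinone) 1 alpha subcomplex 12	1e-31
23636	PT	Helobdella robusta	NADH dehydrogenase (ubiquinone) 1 alpha subcomplex 12	1e-34
23636	PT	Lottia gigantea	NADH dehydrogenase (ubiquinone) 1 alpha subcomplex 12	1e-33
23729	A	Platynereis dumerilii	trans-2,3-enoyl-CoA reductase (TECR)	1e-104
23729	A	Eulalia clavigera	trans-2,3-enoyl-CoA reductase (TECR)	1e-96
23729	PT	Capitella teleta	trans-2,3-enoyl-CoA reductase (TECR)	1e-115
23729	PT	Helobdella robusta	trans-2,3-enoyl-CoA reductase (TECR)	1e-97
23729	PT	Lottia gigantea	trans-2,3-enoyl-CoA reductase (TECR)	1e-117
23816	A	Malacoceros fuliginosus	Aldolase A	1e-105
23816	A	Capitella teleta	Aldolase C	0
23816	B	Ridgeia piscesae	Aldolase A	0
23816	B	Crassostrea gigas	Aldolase A	0
23816	PT	Helobdella robusta	Aldolase C	1e-177
23816	PT	Lottia gigantea	Aldolase A	1e-169
24126	A	Lottia gigantea	xin actin-binding repeat containing 2 (XIRP2)	1e-13
24126	A	Themiste lageniformis	LIM and SH3 domain protein 1-like	1e-12
24126	PT	Helobdella robusta	cysteine- and glycine-rich protein 3 (cardiac LIM protein)	1e-15
24126	PT	Capitella teleta	cysteine- and glycine-rich protein 3 (cardiac LIM protein)	1e-9
RPL24	A	Lanice conchilega	RPL24 domain containing 1	1e-27
RPL24	A	Eisenia fetida	RPL24 domain containing 1	1e-28
RPL24	PT	Capitella teleta	RPL24	1e-59
RPL24	PT	Helobdella robusta	RPL24	1e-48
RPL24	PT	Lottia gigantea	RPL24	1e-50
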