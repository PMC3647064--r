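partition	clade	class	support	leading_branch_length	branch_ratio
22431	A	no_paralog	98	0.0379	0.98
22539	A+B	no_paralog	96	0.1997	1.22
23729	A	no_paralog	96	0.1466	1.51
22938	A	no_paralog	98	0.3748	2.37
22636	A	no_paralog	98	0.2843	2.46
23018	A	no_paralog	98	0.1003	2.57
22539	A	no_paralog	100	0.6049	3.70
23816	A	potential_paralog	96	0.0834	0.77
24126	A	potential_paralog	97	0.1497	1.57
21904	B	potential_paralog	98	0.2313	1.87
21904	A	potential_paralog	99	0.2362	1.91
22606	A	potential_paralog	100	0.9936	4.40
23816	B	potential_paralog	100	0.543	5.00
22680	A	potential_paralog	99	0.2545	5.24
RPL24	A	potential_paralog	96	1.7501	7.45
23636	A	potential_paralog	99	4.1402	10.17
22433	A	potential_paralog	100	4.1762	13.40
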