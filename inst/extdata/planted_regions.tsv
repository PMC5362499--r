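region	gene
linear_1	g6
linear_1	g7
linear_1	g8
linear_1	g9
linear_1	g10
linear_1	g11
linear_1	g12
erbb_1	GRB2
erbb_1	SOS1
erbb_1	KRAS
erbb_1	RAF1
erbb_1	MAP2K1
erbb_1	MAPK1
erbb_1	MAPK3
erbb_2	PIK3R1
erbb_2	PIK3CA
erbb_2	AKT1
erbb_2	MTOR
erbb_2	RPS6KB1
erbb_2	GSK3B
erbb_2	BAD
erbb_3	NCK1
erbb_3	PAK1
erbb_3	MAP2K4
erbb_3	MAPK8
erbb_3	JUN
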