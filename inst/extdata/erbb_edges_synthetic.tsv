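gene_a	gene_b
EGF	EGFR
TGFA	EGFR
AREG	EGFR
BTC	EGFR
BTC	ERBB4
HBEGF	EGFR
HBEGF	ERBB4
EREG	EGFR
EREG	ERBB4
NRG1	ERBB3
NRG1	ERBB4
NRG2	ERBB3
NRG2	ERBB4
NRG3	ERBB4
NRG4	ERBB4
EGFR	ERBB2
ERBB2	ERBB3
ERBB2	ERBB4
EGFR	SHC1
EGFR	GRB2
EGFR	PLCG1
EGFR	CBL
EGFR	STAT5A
EGFR	NCK1
EGFR	CRK
ERBB2	SHC1
ERBB2	GRB2
ERBB2	PLCG1
ERBB2	NCK1
ERBB3	PIK3R1
ERBB4	SHC1
ERBB4	PIK3R1
ERBB4	STAT5A
SHC1	GRB2
GRB2	GAB1
GAB1	PIK3R1
CRK	ABL1
GRB2	SOS1
SOS1	KRAS
SOS1	HRAS
KRAS	RAF1
HRAS	RAF1
KRAS	BRAF
RAF1	MAP2K1
RAF1	MAP2K2
BRAF	MAP2K1
MAP2K1	MAPK1
MAP2K1	MAPK3
MAP2K2	MAPK1
MAP2K2	MAPK3
MAPK1	ELK1
MAPK3	ELK1
MAPK1	MYC
STAT5A	MYC
PLCG1	PRKCA
PLCG1	PRKCB
PIK3R1	PIK3CA
PIK3CA	AKT1
AKT1	MTOR
MTOR	RPS6KB1
MTOR	EIF4EBP1
AKT1	GSK3B
AKT1	BAD
AKT1	MDM2
AKT1	CDKN1A
AKT1	CDKN1B
NCK1	PAK1
PAK1	MAP2K4
MAP2K4	MAPK8
MAPK8	JUN
MAPK8	ELK1
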