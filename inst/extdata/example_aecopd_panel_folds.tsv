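seq_id	symbol	direction	AE1_vs_CON	AE1_vs_STABLE	AE3_vs_CON	AE3_vs_STABLE	AE10_vs_CON	AE10_vs_STABLE
BC004490	FOS	up	27.4	28.6	33.5	34.9	13.2	13.7
BC015492	IFI27	up	12.3	10.3	13.1	11.0	21.6	18.1
NM_001554	CYR61	up	12.0	40.3	11.2	37.6	11.7	39.2
NM_001901	CTGF	up	35.7	26.6	36.9	27.5	59.3	44.2
NM_003979	GPRC5A	up	21.2	12.6	19.2	11.4	75.8	45.1
NM_006732	FOSB	up	21.7	13.7	40.1	25.3	35.6	22.5
NM_133504	DCN	up	19.0	17.2	19.6	17.8	20.0	18.1
XM_373497	LOC387763	up	41.4	13.5	46.4	15.2	41.3	13.5
AJ002102	KIR2DS2	down	3.7	3.8	7.4	7.6	4.2	4.4
BC022407	SH2D1B	down	3.0	3.7	4.8	5.9	3.1	3.8
BC066595	SH2D1B	down	3.6	3.2	9.9	8.9	3.6	3.2
BC100911	CD8B	down	11.2	4.4	16.0	6.3	7.9	3.1
NM_001004698	OR2W5	down	3.7	3.1	4.7	4.0	3.7	3.1
NM_004931	CD8B	down	10.3	5.3	11.5	5.9	6.6	3.4
NM_031950	KSP37	down	4.8	5.0	9.8	10.2	3.0	3.1
NM_201633	TCF7	down	15.6	5.6	30.4	10.8	8.9	3.2
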