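seq_id	symbol	direction	STABLE_vs_CON	AE1_vs_CON	AE3_vs_CON	AE10_vs_CON
D12502	CEACAM1	up	10.1	83.0	66.5	10.5
NM_004369	COL6A3	up	10.4	21.0	22.4	10.8
AF064599	NOL3	up	12.1	13.6	16.3	11.5
BC042586	COL1A2	up	13.1	72.3	92.9	17.2
BC014473	CEACAM1	up	14.7	101.2	61.0	11.8
AY358857	MLPH	up	17.0	10.3	12.8	12.2
AF348143	MUC1	up	20.0	19.7	20.1	28.6
NM_012385	P8	up	20.1	19.1	21.3	22.1
BC093946	UNQ473	up	20.2	45.9	53.1	24.3
NM_001305	CLDN4	up	23.0	34.4	39.1	20.7
NM_002933	RNASE1	up	26.9	12.5	15.2	37.2
BC053636	H19	up	29.5	37.2	28.0	11.8
BC069423	DEFA1	up	33.0	96.1	86.7	10.2
XM_928349	LOC653600	up	43.1	115.8	109.4	12.8
M38056	HLA-DOA	down	5.3	5.9	5.6	7.3
AY209188	SAA3P	down	5.3	6.7	6.4	11.9
BC069511	UBASH3A	down	5.5	10.4	14.3	6.9
AJ421515	CRTAC1	down	5.6	25.4	12.5	11.9
AL133666	EPHA6	down	5.6	5.8	8.2	5.3
NM_020152	C21orf7	down	5.7	8.2	9.7	10.4
XM_089384	TTC24	down	5.8	11.7	12.5	12.7
NM_006850	IL24	down	6.0	6.5	10.7	11.1
AL713701	C21orf7	down	6.1	9.5	9.5	10.0
XM_931594	LOC643514	down	6.2	11.4	5.7	7.4
NM_006159	NELL2	down	6.3	11.5	7.3	10.0
NM_002348	LY9	down	6.7	8.2	7.4	6.5
XM_934852	LOC129293	down	6.9	14.5	12.9	9.4
BC062589	LY9	down	6.9	7.3	7.1	5.5
XM_934149	KIAA0748	down	7.0	7.5	11.2	6.2
BC008567	C21orf7	down	7.3	6.3	7.5	7.7
NM_138363	CCDC45	down	7.8	6.4	5.9	5.2
BC022101	UNQ470	down	7.8	44.1	18.1	32.3
BC027920	LY9	down	7.9	6.2	5.8	5.3
BC033896	AK5	down	8.2	8.2	10.6	9.9
XM_085151	YLPM1	down	10.7	8.7	5.1	7.4
NM_014553	TFCP2L1	down	16.1	21.8	32.0	14.9
NM_001007098	SCP2	down	21.0	27.9	18.7	18.6
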