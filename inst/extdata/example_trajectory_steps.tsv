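seq_id	symbol	pattern	step1_fold	step2_fold
NM_000032	ALAS2	down-down	6.4	6.5
BC099627	EPB42	down-down	9.9	4.4
BC027890	CA1	down-down	21.6	5.1
AK127453	NA	down-up	4.7	5.7
NM_003944	SELENBP1	down-up	5.6	4.1
BC090921	MYH9	down-up	6.2	4.1
NM_181717	HCG27	up-down	4.1	7.3
NM_177551	GPR109A	up-down	4.3	7.5
NM_006018	GPR109B	up-down	4.4	5.1
AF249277	MTHFS	up-down	4.6	5.3
AY234180	BCL2A1	up-down	5.2	4.0
BC010952	PI3	up-down	6.0	4.4
NM_002243	KCNJ15	up-down	7.0	4.8
Z15108	PRKCZ	up-up	2.0	2.8
BC037798	CGI-38	up-up	2.0	2.4
NM_001033581	PRKCZ	up-up	2.1	2.8
NM_007168	ABCA8	up-up	2.1	4.0
AK022468	SORBS1	up-up	2.3	3.5
NM_006403	NEDD9	up-up	2.3	2.2
NM_023037	FRY	up-up	2.3	2.1
NM_016730	FOLR1	up-up	3.0	11.7
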