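seq_id	symbol	pattern	AE1	AE3	AE10
NM_000032	ALAS2	down-down	17.64	2.76	-2.37
BC099627	EPB42	down-down	10.02	1.01	-4.37
BC027890	CA1	down-down	103.93	4.81	-1.06
AK127453	NA	down-up	-1.69	-7.90	-1.38
NM_003944	SELENBP1	down-up	3.97	-1.41	2.92
BC090921	MYH9	down-up	-1.36	-8.40	-2.04
NM_181717	HCG27	up-down	1.09	4.47	-1.63
NM_177551	GPR109A	up-down	4.12	17.79	2.36
NM_006018	GPR109B	up-down	2.64	11.64	2.28
AF249277	MTHFS	up-down	4.51	20.75	3.95
AY234180	BCL2A1	up-down	2.38	12.45	3.11
BC010952	PI3	up-down	1.03	6.20	1.42
NM_002243	KCNJ15	up-down	2.25	15.78	3.26
Z15108	PRKCZ	up-up	-1.25	1.61	4.46
BC037798	CGI-38	up-up	-5.87	-2.86	-1.18
NM_001033581	PRKCZ	up-up	-1.61	1.30	3.64
NM_007168	ABCA8	up-up	-1.27	1.68	6.69
AK022468	SORBS1	up-up	1.28	2.92	10.30
NM_006403	NEDD9	up-up	2.43	5.57	12.15
NM_023037	FRY	up-up	-1.11	2.08	4.34
NM_016730	FOLR1	up-up	-4.20	-1.39	8.39
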