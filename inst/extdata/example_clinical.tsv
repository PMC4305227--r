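group	subject	age	smoking	fev1_fvc_pct	fev1_pred_pct	goddard
CON	1	56	nonsmoker	75	85	0
CON	2	53	nonsmoker	80	87	0
CON	3	62	nonsmoker	77	91	0
CON	4	68	nonsmoker	81	83	0
CON	5	58	nonsmoker	79	81	0
CON	6	67	nonsmoker	76	90	0
STABLE	1	71	ex-smoker	57	47	10
STABLE	2	75	ex-smoker	46	66	6
STABLE	3	61	ex-smoker	46	47	8
STABLE	4	57	ex-smoker	38	29	12
STABLE	5	59	ex-smoker	67	66	7
STABLE	6	53	ex-smoker	29	36	11
AECOPD	1	77	ex-smoker	40	42	10
AECOPD	2	72	ex-smoker	36	27	11
AECOPD	3	65	ex-smoker	28	33	16
AECOPD	4	56	ex-smoker	48	61	6
AECOPD	5	61	ex-smoker	69	55	4
AECOPD	6	67	ex-smoker	56	60	8
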