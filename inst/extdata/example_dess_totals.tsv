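patient	CON	STABLE	AE1	AE3	AE10
1	0	30	100	78	43
2	4	27	81	66	46
3	8	35	86	76	36
4	4	55	70	51	30
5	3	38	80	71	35
6	0	47	97	81	30
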