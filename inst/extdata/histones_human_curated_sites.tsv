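id	position	label
HsH3.1	4	P
HsH3.1	9	P
HsH3.1	14	P
HsH3.1	18	P
HsH3.1	23	P
HsH3.1	27	P
HsH3.1	36	P
HsH3.1	37	P
HsH3.1	56	P
HsH3.1	64	N
HsH3.1	79	N
HsH3.1	115	N
HsH3.1	122	N
HsH4	5	P
HsH4	8	P
HsH4	12	P
HsH4	16	P
HsH4	20	N
HsH4	31	P
HsH4	44	P
HsH4	59	P
HsH4	77	P
HsH4	79	P
HsH4	91	P
HsH2B.1	5	P
HsH2B.1	11	P
HsH2B.1	12	P
HsH2B.1	15	P
HsH2B.1	16	P
HsH2B.1	20	P
HsH2B.1	23	P
HsH2B.1	24	P
HsH2B.1	27	N
HsH2B.1	28	N
HsH2B.1	30	N
HsH2B.1	34	N
HsH2B.1	43	N
HsH2B.1	46	N
HsH2B.1	57	N
HsH2B.1	85	N
HsH2B.1	108	N
HsH2B.1	116	N
HsH2B.1	120	N
HsH2B.1	125	N
HsH2A.1	5	P
HsH2A.1	9	P
HsH2A.1	13	N
HsH2A.1	15	N
HsH2A.1	36	N
HsH2A.1	74	N
HsH2A.1	75	N
HsH2A.1	95	N
HsH2A.1	99	N
HsH2A.1	118	N
HsH2A.1	119	N
HsH2A.1	125	N
HsH2A.1	127	N
HsH2A.1	129	N
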