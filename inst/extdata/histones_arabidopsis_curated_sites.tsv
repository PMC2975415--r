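id	position	label
AtH3.2	4	P
AtH3.2	9	P
AtH3.2	14	P
AtH3.2	18	P
AtH3.2	23	P
AtH3.2	27	P
AtH3.2	36	P
AtH3.2	37	N
AtH3.2	56	N
AtH3.2	64	N
AtH3.2	79	N
AtH3.2	90	N
AtH3.2	115	N
AtH3.2	122	N
AtH3.3	4	P
AtH3.3	9	P
AtH3.3	14	P
AtH3.3	18	P
AtH3.3	23	P
AtH3.3	27	P
AtH3.3	36	P
AtH3.3	37	N
AtH3.3	56	N
AtH3.3	64	N
AtH3.3	79	N
AtH3.3	90	N
AtH3.3	115	N
AtH3.3	122	N
AtH4	5	P
AtH4	8	P
AtH4	12	P
AtH4	16	P
AtH4	20	P
AtH4	31	N
AtH4	44	N
AtH4	59	N
AtH4	77	N
AtH4	79	N
AtH4	91	N
AtH2B.6	3	P
AtH2B.6	6	P
AtH2B.6	7	P
AtH2B.6	11	P
AtH2B.6	12	P
AtH2B.6	17	P
AtH2B.6	22	N
AtH2B.6	24	N
AtH2B.6	27	N
AtH2B.6	31	N
AtH2B.6	32	N
AtH2B.6	34	N
AtH2B.6	38	N
AtH2B.6	47	N
AtH2B.6	50	N
AtH2B.6	61	N
AtH2B.6	89	N
AtH2B.6	112	N
AtH2B.6	120	N
AtH2B.6	124	N
AtH2B.6	129	N
AtH2B.7	3	P
AtH2B.7	6	P
AtH2B.7	7	P
AtH2B.7	11	P
AtH2B.7	12	P
AtH2B.7	17	P
AtH2B.7	22	N
AtH2B.7	24	N
AtH2B.7	27	N
AtH2B.7	31	N
AtH2B.7	32	N
AtH2B.7	34	N
AtH2B.7	38	N
AtH2B.7	47	N
AtH2B.7	50	N
AtH2B.7	61	N
AtH2B.7	89	N
AtH2B.7	112	N
AtH2B.7	120	N
AtH2B.7	124	N
AtH2B.7	129	N
AtH2B.10	3	P
AtH2B.10	6	P
AtH2B.10	7	P
AtH2B.10	11	P
AtH2B.10	12	P
AtH2B.10	17	P
AtH2B.10	22	P
AtH2B.10	24	N
AtH2B.10	27	N
AtH2B.10	31	N
AtH2B.10	32	N
AtH2B.10	34	N
AtH2B.10	38	N
AtH2B.10	47	N
AtH2B.10	50	N
AtH2B.10	61	N
AtH2B.10	89	N
AtH2B.10	112	N
AtH2B.10	120	N
AtH2B.10	124	N
AtH2B.10	129	N
AtH2A.4	5	P
AtH2A.4	9	N
AtH2A.4	13	N
AtH2A.4	15	N
AtH2A.4	36	N
AtH2A.4	74	N
AtH2A.4	75	N
AtH2A.4	95	N
AtH2A.4	99	N
AtH2A.4	118	N
AtH2A.4	119	N
AtH2A.4	125	N
AtH2A.4	127	N
AtH2A.4	129	N
AtH2A.4	134	N
AtH2A.4	144	P
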