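subject	PRE_OFF	PRE_ON	POST_OFF	POST_ON
P01	21	5	24	9
P02	44	9	32	13
P03	36	10	28	12
P04	47	20	28	8
P05	31	10	21	12
P06	43	9	24	6
P07	64	18	39	21
P08	46	21	24	8
P09	18	8	19	13
P10	33	7	27	10
P11	35	4	14	3
P12	34	15	33	15
P13	19	6	17	7
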