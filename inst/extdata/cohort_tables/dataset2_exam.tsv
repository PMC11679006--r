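participant	nfogq	updrs3	froze
P12	18	6.5	TRUE
P13	29	28	TRUE
P14	15	17	TRUE
P15	19	14.5	TRUE
P16	23	20.5	TRUE
P17	29	20	TRUE
P05B	15	NA	TRUE
P07B	26	11	TRUE
P08B	10	10	TRUE
P11B	22	22	TRUE
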