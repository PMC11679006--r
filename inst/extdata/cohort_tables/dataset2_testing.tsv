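participant	n_trials	total_duration	n_fog	total_fog_duration	mtd_zone_duration
P12	12	457.20	9	9.90	57.40
P13	29	1436.37	41	67.24	207.20
P14	27	1472.58	23	63.25	233.80
P15	28	1353.80	34	93.84	NA
P16	28	1872.08	28	370.72	NA
P17	26	1907.36	83	678.94	516.60
P05B	23	1176.91	8	50.32	180.60
P07B	29	2268.96	126	496.44	676.20
P08B	29	1318.05	1	0.73	120.40
P11B	22	2461.80	75	324.00	NA
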