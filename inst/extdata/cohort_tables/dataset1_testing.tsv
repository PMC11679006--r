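participant	n_trials	total_duration	n_fog	total_fog_duration	mtd_zone_duration
P01	26	881.4	49	33.81	98
P02	26	1199.9	35	92.4	99.4
P03	29	1456.09	14	14.84	91
P04	14	547.96	0	0	NA
P05	24	1100.16	0	0	NA
P06	29	1964.46	10	42.3	155.4
P07	26	2024.62	221	335.92	410.2
P08	22	1057.76	24	36.24	127.4
P09	28	1445.36	9	6.75	98
P10	29	1251.64	0	0	NA
P11	29	1867.89	0	0	NA
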