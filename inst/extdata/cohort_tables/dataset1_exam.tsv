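participant	nfogq	updrs3	froze
P01	14	10	TRUE
P02	21	20	TRUE
P03	17	13	TRUE
P04	4	18	FALSE
P05	20	13	FALSE
P06	22	29	TRUE
P07	15	16	TRUE
P08	17	20	TRUE
P09	18	18	TRUE
P10	4	15	FALSE
P11	19	20	FALSE
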