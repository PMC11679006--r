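participant	age	years_since_diagnosis
P01	67	16
P02	80	11
P03	71	11
P04	64	10
P05	70	14
P06	68	19
P07	78	5
P08	70	12
P09	80	10
P10	80	2
P11	72	5
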