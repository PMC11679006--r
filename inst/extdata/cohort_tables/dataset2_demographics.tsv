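participant	age	years_since_diagnosis
P12	74	4
P13	66	19
P14	69	19
P15	81	3
P16	67	6
P17	58	11
P05B	72	17
P07B	81	8
P08B	73	14
P11B	74	8
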