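dataset	n	sensitivity	specificity	pct_identified	pct_predicted	pct_detected	mean_id
1	11	75.40	83.08	74.31	40.61	51.93	-0.64
2	10	82.50	77.27	94.86	57.01	80.14	-1.10
3	21	77.68	79.99	86.84	49.11	68.48	-0.94
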