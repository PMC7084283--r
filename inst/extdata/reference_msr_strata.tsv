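group	n_before	n_total	rate_pct
msr_le_2	429	2328	19.13
msr_gt_2	1382	10107	16.81
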