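condition	median_lag_days	n_hospital_before_daq	n_with_hospital	n_total
endometrial cancer	2.5	46	72	110
esophageal cancer	14.3	45	66	119
lymphoma	6.6	304	478	849
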