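n_recognized	n_responses	sham_correct_pct
3987	4636	74
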