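unit	stratum	n_multi_lines	n_lines	fraction_pct
NOTCH	ALL	5	45	11.111111
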