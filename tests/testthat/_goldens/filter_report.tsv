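filter_name	records_in	records_out
noncoding	55	51
silent	51	47
low_allelic_fraction	47	45
notch4_repeat_window	45	43
small_cell_types	43	43
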